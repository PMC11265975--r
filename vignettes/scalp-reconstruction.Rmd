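---
title: "Reconstructing the scalp surface from sparse pointer samples"
author: "scalpfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing the scalp surface from sparse pointer samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scalpfit)
```

## The problem

Neuronavigation for TMS, EEG and related procedures needs the subject's
scalp surface and a registration of the head into the navigation frame.
The conventional workflow annotates three fiducials (nasion, left and
right preauricular points), possibly four more "extremities", and fits a
head template by a similarity transform — accurate only to several
millimeters, and better workflows require an individual MRI. The
alternative implemented here needs neither: an operator sweeps a tracked
pointer over the scalp, producing a sparse, unordered trajectory of
surface samples covering a few percent of the head, and a statistical
shape prior fills in the rest.

## The model

A linear statistical shape model (3D morphable model) represents a head
surface in dense vertex correspondence as

$$S_w = S_{\text{mean}} + \sum_{i=1}^{k} w_i \, e_i \, v_i,$$

where the $v_i$ are unit-norm, mutually orthogonal eigenvectors of the
training covariance and $e_i$ the corresponding mode *standard
deviations*. Storing the square root of the covariance eigenvalue (rather
than the eigenvalue itself) makes the weights $w_i$ standard normal over
the training population, so a Frobenius-norm penalty on $w$ acts in
interpretable SD units; imported models can declare a different
convention in their container manifest.

Fitting couples this shape model with a non-uniform similarity transform
$T$ (per-axis scale $s \in \mathbb{R}^3_{>0}$, rotation $R$, translation
$t$). Given samples $x \in S_{\text{sampled}}$ the objective is

$$\mathrm{loss} = \lambda_1 \, cd + \lambda_2 \, cn +
  \lambda_3 \lVert w \rVert_F + \lambda_4 \lVert T - T_0 \rVert_F,$$

with the one-sided Chamfer term
$cd = \frac{1}{|S|}\sum_x \min_y d(x, y)$ taken only from the samples —
a sparse trajectory must never be asked to explain the whole model
surface — and $cn$ an optional sign-invariant cosine distance between
sample normals and the corresponding surface normals. $T_0$ is a coarse,
annotation-free initialization (centroid, principal-axis extents and
principal-axis rotation, with the best of the four proper sign
assignments chosen by Chamfer distance). Because a subject whose shape
reverses the template's asymmetries can fool that one-shot choice,
`fit_scalp()` by default gives each of the four candidates a short trial
optimization and continues from the best (`multi_start = FALSE` disables
the trials when the initialization is trusted or supplied). Both $w$ and $T$ are
optimized
*simultaneously* by Adam; the scale is parameterized on the log scale so
it cannot be driven non-positive, and the rotation as an axis-angle
vector, leaving the problem unconstrained. Gradients are analytic:
correspondences are recomputed at every iteration and held fixed within
an iteration's gradient, the standard treatment of nearest-neighbor
assignments.

### Defaults and units

`fit_config()` mirrors the study settings: $\lambda = (10, 1, 1, 1)$,
Adam with learning rate $10^{-3}$, at most 1000 iterations with early
stopping (patience 50 iterations, minimum improvement $10^{-6}$), 50
model components, and the loss computed in centimeters. Mesh coordinates
at the interface are millimeters; the conversion happens inside the fit.
The normal term is off by default: normals estimated from a sparse real
trajectory by local PCA are noisy, and the term mainly helps when dense,
reliable normals exist. Early stopping parameters are a package choice —
"stops improving over multiple epochs" admits many realizations — and are
exposed in the configuration.

### Correspondence: surface, not vertex

The Chamfer *quantity* (`one_sided_chamfer()`) pairs points with points.
Inside the optimizer, however, the default correspondence is the exact
closest point on the reconstructed triangle surface, with gradients
distributed barycentrically over the face vertices
(`fit_config(correspondence = "vertex")` restores the point-to-point
variant). The reason is resolution: pairing with vertices floors the
attainable accuracy at about half the mesh edge length, which is
negligible for a model with tens of thousands of vertices but ~4 mm on
the 1026-vertex meshes this package's studies run at. In the dense-mesh
limit the two coincide; on coarse meshes the surface correspondence is
the faithful realization of "distance to the model surface".

### Regularization and identifiability

The two Frobenius penalties encode priors: weights are standard normal
(so $\lVert w \rVert$ penalizes improbable shapes), and the pose should
not stray far from its initialization. They matter for sparse, partial,
noisy trajectories. For *dense noise-free* data they are not only
unnecessary but biased in a specific, instructive way: a smooth closed
surface admits near-isometric "sliding" fields — combinations of shape
weights and pose that move vertices tangentially while barely changing
the surface — and any penalty pressure travels far along these
near-flat valleys. Parameter-recovery experiments therefore run with
$\lambda_3 = \lambda_4 = 0$ (the maximum-likelihood limit), under which
recovery of weights, rotation, scale and translation is exact to
numerical precision; the virtual sampling study keeps the sparse-data
defaults.

## Sampling simulators

Four walk strategies on the mesh edge graph (Euclidean edge weights)
emulate how an operator sweeps a pointer: `side_to_top` (a zigzag pass
over each hemisphere), `half_side_to_top` (one hemisphere only),
`side_to_side` (one pass crossing the midline), and `random_walk`
(uniform random adjacent moves until a target length). For the non-random
strategies the head is divided into `n_steps + 1` sections of equal
angular extent along the front-over-top-to-back arc, each split into
three equal-angle sub-sections by latitude from the midline. Every step
is a Dijkstra shortest path from a seeded-random vertex in one section to
one in the next, restricted to those two sections; step endpoints
alternate between the low and high sub-sections, which is what produces
the vertical zigzag. The first step starts at the pre-auricular area (the
lateral extreme of the first section's low sub-section). Steps are
semi-continuous: contiguous along edges within a step, with short seeded
jumps between steps, and the trajectory length is the accumulated
Euclidean distance over consecutive points. Sample normals are estimated
from the samples alone (smallest-variance direction of the local k-NN
covariance, oriented away from the head center, radial fallback for
collinear neighborhoods).

Every simulator is a pure function of its seed; identical seeds give
bitwise-identical trajectories.

## The benchmark

The comparison method mirrors conventional landmark registration: a
closed-form least-squares similarity transform (Umeyama; reflections
disallowed) maps the template's annotated landmarks onto the subject's —
either the 3 fiducials or 7 (adding the topmost/backmost/leftmost/
rightmost extremities) — and the posed template mean is the
reconstruction. Vendor tools also deform the template towards the
landmarks, but the deformation is proprietary and undocumented;
pose-only reconstruction is the reproducible core shared by those tools,
and the choice is recorded here rather than guessed at. Extremities are
taken at corresponded vertices by default (the precise variant dense
correspondence affords); an operator-style coordinate-extreme picker is
available.

## The synthetic study

No licensed head model or MRI collection ships with this package, so the
generator plays their role with known ground truth:

* **Template**: a superellipsoid head (front/back semi-axes 93/103 mm,
  lateral 76 mm, up 92 mm, flattened base 66 mm; exponent 2.4) sampled on
  a subdivided octahedron (exactly mirror-symmetric; resolution 4 gives
  1026 vertices), with localized brow, occiput and preauricular
  prominences. Horizontal circumference is ~560 mm, the adult average, so
  trajectory lengths are physically meaningful. The prominences matter:
  on a featureless near-ellipsoid, pose is not identifiable from surface
  distance — rotations slide the surface into itself — just as a real
  featureless scalp would not pin registration without ears and brow.
* **Modes**: smooth radial fields driven by low-order polynomials of the
  outward direction (cephalic-index, crown-base, occipital-tilt, ...),
  projected orthogonal to the 9-dimensional similarity-pose tangent space
  and orthonormalized. The projection is the synthetic analogue of
  Procrustes-aligning scans before PCA: real model pipelines remove
  pose-like variation from the modes, and without it shape and pose are
  confounded by construction. Default amplitudes (250, 160, 100 mm in the
  flattened-norm convention) correspond to per-vertex RMS displacements
  of roughly 8, 5, 3 mm on the default template — the scale of adult
  head-shape variability.
* **Subjects**: drawn from the generator with standard-normal weights and
  modest random poses (scales within ±4%, rotations within ~5 degrees,
  translations within ±20 mm), optionally with isotropic vertex jitter
  emulating pointer noise.

`run_virtual_study()` chains everything: a 100-mesh training population,
a PCA model rebuilt from it, 20 held-out subjects × 5 walks with budgets
drawn from 1–16 steps, joint fits at the sparse-data defaults, and both
benchmarks, yielding a tidy table for the binning and regression
machinery. The desk-scale sizes (1026 vertices, 20 × 5 fits) are the
package's study conditions; the original investigation this emulates ran
1152 subjects at MRI resolution.

What passing this study shows — and what it does not: the synthetic
population is exactly low-rank, exactly corresponded, and hair, skin
deformation, tracker drift and operator error do not exist here.
Synthetic results therefore validate the estimator and its error
characterization, not clinical accuracy. Conversely the qualitative
structure — error decreasing with trajectory length to a plateau well
below the landmark benchmark, with the 7-landmark benchmark between —
is the pattern the method exhibits at full scale.

## Error predictability

Reconstruction error is modeled as a function of trajectory length with
an exponential decay $f(x) = a e^{bx} + c$ (Levenberg–Marquardt with
multiple starts) or polynomials of degree 3–7 (ordinary least squares).
Goodness of fit is the Pearson chi-squared statistic of the 200 mm-binned
mean RMSE against the model at the bin centers; the statistic needs a
definition of observed and expected, and binned means against bin-center
predictions is the one consistent with the 200 mm confidence-interval
binning used throughout (normal-approximation 95% half-widths
$1.96\,\mathrm{SD}/\sqrt{n}$; single-observation bins are flagged and
carry zero width by convention). The lab-style protocol is also
implemented: pooled trajectories are cut into 20 contiguous
equal-count segments, fits use a random 75% of segments and are scored
on the held-out 25% (stratified so both hemispheres and several
front-to-back regions are represented; an infeasible stratification
falls back to a plain random split, with a flag), repeated 10 times.

## Numerical choices and degenerate inputs

* Nearest neighbors are exhaustive-scan with ties broken by the lowest
  index — exact and deterministic at these problem sizes.
* Eigenvector signs are fixed by making the largest-magnitude entry
  positive; components with SD below $10^{-8}$ of the leading one are
  dropped.
* Degenerate (zero-area) faces contribute no normal; an all-degenerate
  mesh is an error. Outward orientation is decided per connected
  component by majority vote against the centroid ray.
* A rank-deficient sample spread in `coarse_init()` falls back to
  isotropic scale and is flagged; collinear landmark sets are an error.
* Non-finite losses abort with a diagnostic rather than propagate.
* Vertex normals on a tessellated sphere deviate from the radial
  direction by $O(h)$ in the edge length $h$ for any area-weighted
  scheme; tests assert the measured level and its halving under
  subdivision rather than an idealized zero.

## Limitations

Vertex-to-vertex RMSE against a 1026-vertex ground truth cannot resolve
errors much below the millimeter scale except under exact parameter
recovery; the surface-distance variant (`position_rmse(to_surface =
TRUE)`) is provided where that matters. The benchmark is pose-only, as
discussed. Real pointer streams (vendor formats), hair occlusion, and
MRI segmentation are out of scope; trajectories enter as plain CSV.
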