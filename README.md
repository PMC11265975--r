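# scalpfit

Scalp surface reconstruction and head registration from sparse surface
samples.

Neuronavigation procedures (TMS targeting, EEG electrode placement) need
the subject's scalp surface registered into the navigation frame.
Conventional workflows rely on manually annotated fiducial landmarks and
often an individual MRI. `scalpfit` implements an alternative: an
operator sweeps a tracked pointer over the scalp, producing a sparse,
unordered trajectory that covers a few percent of the head, and a linear
statistical shape model (3D morphable model) of the head supplies the
rest. The package jointly optimizes a non-uniform similarity transform
and the model's shape weights against a regularized one-sided Chamfer
loss:

    S_w  = S_mean + sum_i w_i * e_i * v_i
    loss = lambda1 * cd + lambda2 * cn
           + lambda3 * ||w||_F + lambda4 * ||T - T0||_F

where `cd` is the mean (squared) distance from each sample to the posed,
morphed surface, `cn` an optional normal-consistency term, and `T0` an
annotation-free coarse initialization. Optimization is Adam on analytic
gradients, with the scale log-parameterized and the rotation in
axis-angle form.

Around the estimator the package provides:

* mesh and point-cloud utilities (PLY/OBJ I/O, vertex normals, edge
  graphs, exact point-to-surface distances);
* PCA construction of shape models from corresponded meshes, instance
  synthesis, truncation, a plain-text model container;
* simulators for the four scalp-sampling strategies (side-to-top,
  side-to-side, half side-to-top, random walk) as seeded walks on the
  mesh edge graph;
* the landmark-registration benchmark (3 or 7 fiducials, closed-form
  similarity transform);
* evaluation: position-displacement RMSE, 200 mm binned confidence
  intervals, segment cross-validation, and error-vs-trajectory-length
  regression (exponential decay and polynomial) with Pearson chi-squared
  goodness of fit;
* a synthetic head-population generator with known ground truth, and
  `run_virtual_study()` chaining everything into a tidy results table.

## Worked example

Fit a synthetic subject from a single side-to-top sweep:

```r
library(scalpfit)

template <- make_template_head(resolution = 4)   # 1026-vertex head, mm
model    <- true_model(template)                 # 3-mode shape model
subject  <- make_subject(model, w_true = c(1.1, -0.6, 0.4),
                         pose_true = head_pose(translation = c(12, -5, 8)))

graph    <- build_edge_graph(subject$mesh)
sections <- partition_sections(subject$mesh, graph, n_steps = 8,
                               frame = subject$meta$frame)
traj     <- sample_strategy(subject$mesh, graph, sections,
                            "side_to_top", n_steps = 8, seed = 42)
traj
#> trajectory (side_to_top): 197 points, length 2456.7 mm, geodesic 1924.8 mm

fit <- fit_scalp(model, traj)
summary(fit)
#> Joint scalp-surface fit
#>   samples: 197   components: 3   iterations: 1000 (max_iter)
#>   final loss 0.615275  (cd 0.0311261, cn 0, reg 0.304014)
#>   sample residuals: RMSE 1.764 mm, max 5.527 mm
#>   ||w||_F = 0.107
#> head_pose: scale (0.8796, 1.133, 1.009), rotation 1.709 deg, translation (12.49, -4.687, 4.035)

position_rmse(subject$mesh, fit$reconstructed)
#> [1] 4.665051
```

The 197 trajectory points (a 2.5 m sweep; ~18% of mesh vertices lie
within 5 mm of the path) constrain the fit to a 4.7 mm reconstruction
RMSE over the *whole* head, including the unsampled underside. The
3-landmark template registration (`landmark_register()`) reconstructs
the same subject at 11.1 mm. The fitted pose leans on its non-uniform
scale (0.88, 1.13, 1.01) to express part of this subject's long-narrow
head shape — shape weights and anisotropic scale overlap, and the weight
penalty makes the pose carry what it can. `plot(fit)` shows the
loss-term history; `residuals(fit)` the per-sample distances to the
reconstructed surface.

(Numbers are the output of this exact seeded example; a different BLAS
may flip trailing digits.)

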