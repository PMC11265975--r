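#' Subdivided-octahedron sphere mesh
#'
#' A watertight unit-sphere triangulation obtained by midpoint subdivision
#' of the octahedron with re-projection onto the sphere. The construction
#' is exactly mirror-symmetric in all three coordinate planes, which the
#' synthetic head template inherits. After r subdivisions the mesh has
#' `4^r * 4 + 2` vertices, `8 * 4^r` faces and `12 * 4^r` edges.
#'
#' @param resolution number of subdivision rounds (>= 0).
#' @param radius sphere radius.
#' @return a [trimesh()].
#' @export
subdivided_sphere <- function(resolution, radius = 1) {
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, -1))
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  for (r in seq_len(resolution)) {
    edges <- edges_from_faces(f)
    key <- paste(edges[, 1], edges[, 2])
    mid <- (v[edges[, 1], , drop = FALSE] + v[edges[, 2], , drop = FALSE]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    mid_id <- nrow(v) + seq_len(nrow(edges))
    names(mid_id) <- key
    v <- rbind(v, mid)
    ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
    m12 <- mid_id[ekey(f[, 1], f[, 2])]
    m23 <- mid_id[ekey(f[, 2], f[, 3])]
    m31 <- mid_id[ekey(f[, 3], f[, 1])]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23),
               cbind(m12, m23, m31))
    dimnames(f) <- NULL
  }
  trimesh(v * radius, f, validate = FALSE)
}

#' Synthetic head-like template surface
#'
#' A closed, head-like surface used as the stand-in template for the
#' licensed statistical head models: a superellipsoid with a longer
#' occipital than frontal semi-axis and a flattened base, sampled on the
#' subdivided-octahedron sphere so all derived meshes share an exact dense
#' correspondence. The template carries a canonical head frame (front = +x,
#' left = +y, up = +z, origin at the center) and annotated fiducial
#' landmark vertices (nasion and the two preauricular points) at fixed
#' parametric positions. Default semi-axes give a horizontal circumference
#' of roughly 560 mm — the adult average of about 0.56 m — so trajectory
#' lengths on the synthetic head are physically comparable to real scalps.
#'
#' @param resolution sphere subdivision rounds (>= 2); the default 4 gives
#'   1026 vertices.
#' @param semi_axes named list/vector of semi-axes in mm: `front`, `back`,
#'   `side`, `up`, `down`.
#' @param exponent superellipsoid exponent (2 = ellipsoid; larger values
#'   flatten towards a box).
#' @return a [trimesh()] with attributes `frame` (a [head_frame()]) and
#'   `landmarks` (named vertex indices).
#' @export
make_template_head <- function(resolution = 4,
                               semi_axes = c(front = 93, back = 103,
                                             side = 76, up = 92, down = 66),
                               exponent = 2.4) {
  if (resolution < 2) stop("resolution must be >= 2")
  sph <- subdivided_sphere(resolution)
  d <- sph$vertices
  a <- ifelse(d[, 1] >= 0, semi_axes[["front"]], semi_axes[["back"]])
  c_ax <- ifelse(d[, 3] >= 0, semi_axes[["up"]], semi_axes[["down"]])
  p <- exponent
  rad <- (abs(d[, 1] / a)^p + abs(d[, 2] / semi_axes[["side"]])^p +
            abs(d[, 3] / c_ax)^p)^(-1 / p)
  # localized prominences emulating the anatomical features registration
  # leans on: brow ridge, occipital bun, and the preauricular/ear regions.
  # Without them the surface is a near-ellipsoid on which pose is not
  # identifiable (rotations slide the surface into itself).
  bump <- function(dir, amp, width) {
    dir <- dir / sqrt(sum(dir^2))
    ang <- acos(pmin(1, pmax(-1, drop(d %*% dir))))
    amp * exp(-(ang / width)^2)
  }
  rad <- rad * (1 + bump(c(1, 0, 0.05), 0.08, 0.40) +
                  bump(c(-1, 0, -0.30), 0.05, 0.45) +
                  bump(c(0.10, 1, -0.40), 0.06, 0.35) +
                  bump(c(0.10, -1, -0.40), 0.06, 0.35))
  mesh <- trimesh(d * rad, sph$faces, validate = FALSE)
  frame <- head_frame(origin = c(0, 0, 0))
  nearest_dir <- function(dir) {
    dir <- dir / sqrt(sum(dir^2))
    which.max(drop(d %*% dir))
  }
  landmarks <- c(nasion = nearest_dir(c(1, 0, -0.35)),
                 lpa = nearest_dir(c(0.12, 1, -0.45)),
                 rpa = nearest_dir(c(0.12, -1, -0.45)))
  attr(mesh, "frame") <- frame
  attr(mesh, "landmarks") <- landmarks
  mesh
}

#' Specification of a synthetic head population
#'
#' The generator emulates the statistical structure a linear head model
#' assumes: dense-corresponded surfaces scattered around a template along a
#' few smooth orthonormal modes with Gaussian weights. `mode_amplitudes`
#' are the standard deviations of the flattened displacement along each
#' (unit-norm) mode, in mm; on the default 1026-vertex template the
#' defaults correspond to per-vertex RMS displacements of roughly 8, 5 and
#' 3 mm — the scale of adult head-shape variability.
#'
#' @param n_subjects population size.
#' @param n_modes number of shape modes (<= 8 smooth generators available).
#' @param mode_amplitudes non-increasing per-mode SDs (mm, flattened-vector
#'   convention).
#' @param template_resolution subdivision level of the template.
#' @param noise_sd iid per-coordinate vertex jitter SD (mm).
#' @param seed integer seed.
#' @return a list of class `population_spec`.
#' @export
population_spec <- function(n_subjects = 200L, n_modes = 3L,
                            mode_amplitudes = c(250, 160, 100),
                            template_resolution = 4L, noise_sd = 0,
                            seed = 1L) {
  mode_amplitudes <- as.numeric(mode_amplitudes)
  if (length(mode_amplitudes) != n_modes)
    stop("need one amplitude per mode")
  if (any(diff(mode_amplitudes) > 0))
    stop("mode amplitudes must be non-increasing")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_modes = as.integer(n_modes),
                 mode_amplitudes = mode_amplitudes,
                 template_resolution = as.integer(template_resolution),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "population_spec")
}

# Smooth orthonormal displacement modes on a template: radial fields driven
# by low-order polynomials of the outward direction, projected orthogonal
# to the similarity-pose tangent space (translations, rotations, per-axis
# scales) and then orthonormalized by QR. The projection mirrors how real
# statistical head models are built from Procrustes-aligned scans: pose-like
# variation is removed before the modes are extracted, keeping shape and
# pose separately identifiable. Up to 8 modes.
make_shape_modes <- function(template, n_modes) {
  if (n_modes < 1L || n_modes > 8L) stop("1 to 8 modes supported")
  v <- template$vertices
  n <- nrow(v)
  d <- v / sqrt(rowSums(v^2))
  # tangent fields of the pose family at the identity
  ctr <- sweep(v, 2, colMeans(v))
  pose_fields <- cbind(
    flatten_vertices(cbind(1, 0, 0)[rep(1, n), ]),
    flatten_vertices(cbind(0, 1, 0)[rep(1, n), ]),
    flatten_vertices(cbind(0, 0, 1)[rep(1, n), ]),
    flatten_vertices(cbind(0, -ctr[, 3], ctr[, 2])),
    flatten_vertices(cbind(ctr[, 3], 0, -ctr[, 1])),
    flatten_vertices(cbind(-ctr[, 2], ctr[, 1], 0)),
    flatten_vertices(cbind(ctr[, 1], 0, 0)),
    flatten_vertices(cbind(0, ctr[, 2], 0)),
    flatten_vertices(cbind(0, 0, ctr[, 3])))
  gens <- list(
    function(d) d[, 1]^2 - d[, 2]^2,         # long-headed vs broad-headed
    function(d) d[, 3],                      # crown-base elongation
    function(d) d[, 1] * d[, 3],             # occipital/frontal tilt
    function(d) d[, 3]^2 - d[, 2]^2,         # tall vs broad
    function(d) d[, 2],                      # lateral asymmetry
    function(d) d[, 2] * d[, 3],
    function(d) d[, 1] * d[, 2],
    function(d) d[, 1])                      # front-back asymmetry
  fields <- vapply(gens[seq_len(n_modes)], function(g)
    flatten_vertices(g(d) * d), numeric(3L * n))
  qr_d <- qr(cbind(pose_fields, fields))
  Q <- qr.Q(qr_d)[, 9L + seq_len(n_modes), drop = FALSE]
  for (j in seq_len(ncol(Q))) {
    i <- which.max(abs(Q[, j]))
    if (Q[i, j] < 0) Q[, j] <- -Q[, j]
  }
  Q
}

#' Generate a synthetic head population in dense correspondence
#'
#' Subjects are `template + sum_j z_j * amp_j * mode_j` with standard-normal
#' seeded weights `z`, smooth unit-norm mutually orthogonal modes, and
#' optional iid vertex jitter. All meshes share the template topology.
#'
#' @param template a [make_template_head()] mesh.
#' @param spec a [population_spec()].
#' @return list with `meshes` (list of [trimesh()]), the true `modes`
#'   (3n x k orthonormal matrix), the drawn `weights` (n_subjects x k) and
#'   the `spec`.
#' @export
make_population <- function(template, spec) {
  stopifnot(inherits(template, "trimesh"), inherits(spec, "population_spec"))
  modes <- make_shape_modes(template, spec$n_modes)
  base <- flatten_vertices(template$vertices)
  with_seed(spec$seed, {
    Z <- matrix(rnorm(spec$n_subjects * spec$n_modes), spec$n_subjects)
    meshes <- lapply(seq_len(spec$n_subjects), function(i) {
      x <- base + drop(modes %*% (Z[i, ] * spec$mode_amplitudes))
      if (spec$noise_sd > 0)
        x <- x + rnorm(length(x), sd = spec$noise_sd)
      trimesh(unflatten_vertices(x), template$faces, validate = FALSE)
    })
    list(meshes = meshes, modes = modes, weights = Z, spec = spec)
  })
}

#' Morphable model with known ground-truth modes
#'
#' Wraps a template and its true generator modes/amplitudes as a
#' [morphable_model()] — the model from which held-out study subjects are
#' drawn with known weights.
#'
#' @param template a [make_template_head()] mesh.
#' @param n_modes,mode_amplitudes as in [population_spec()].
#' @return a [morphable_model()] carrying the template's landmarks and
#'   frame.
#' @export
true_model <- function(template, n_modes = 3L,
                       mode_amplitudes = c(250, 160, 100)) {
  modes <- make_shape_modes(template, n_modes)
  morphable_model(template, mode_amplitudes, modes,
                  landmarks = attr(template, "landmarks"),
                  frame = attr(template, "frame"))
}

#' Held-out synthetic subject with known weights and pose
#'
#' The ground-truth mesh is `pose_true` applied to
#' `synthesize(model, w_true)`, optionally jittered per-vertex with
#' isotropic Gaussian noise emulating pointer noise. The returned metadata
#' records everything needed to score recovery.
#'
#' @param model a [morphable_model()].
#' @param w_true weight vector (length <= k).
#' @param pose_true a [head_pose()] (mm).
#' @param sample_noise_sd per-coordinate jitter SD (mm).
#' @param seed seed for the jitter.
#' @return list with `mesh` (ground truth [trimesh()]) and `meta`
#'   (`w_true`, `pose_true`, `noise_sd`, `seed`, and the subject's
#'   [head_frame()] when the model declares one).
#' @export
make_subject <- function(model, w_true, pose_true = head_pose(),
                         sample_noise_sd = 0, seed = NULL) {
  stopifnot(inherits(model, "morphable_model"), inherits(pose_true, "head_pose"))
  gt <- apply_pose(pose_true, synthesize(model, w_true))
  if (sample_noise_sd > 0)
    gt$vertices <- gt$vertices + with_seed(seed, matrix(
      rnorm(length(gt$vertices), sd = sample_noise_sd),
      nrow(gt$vertices)))
  frame <- if (!is.null(model$frame)) transform_frame(model$frame, pose_true)
  list(mesh = gt,
       meta = list(w_true = w_true, pose_true = pose_true,
                   noise_sd = sample_noise_sd, seed = seed, frame = frame))
}

#' Scaled-down virtual sampling study
#'
#' End-to-end emulation of the virtual experiments: a training population
#' is generated and a PCA model built from it; held-out subjects are drawn
#' from the true generator with known weights and random modest poses; each
#' subject is sampled with the requested strategies at walk budgets drawn
#' from `n_steps_range`; every trajectory is fitted jointly and also
#' benchmarked with 3- and 7-landmark registration. Returns a tidy table
#' feeding the binning and error-model machinery.
#'
#' @param n_subjects held-out study subjects.
#' @param n_walks_per_subject sampling walks per subject and strategy.
#' @param strategies subset of the four sampling strategies.
#' @param n_steps_range integer range the walk budget is drawn from.
#' @param spec a [population_spec()] for the training population and truth.
#' @param n_train training meshes used to build the PCA model.
#' @param config a [fit_config()] for the joint fits.
#' @param sample_noise_sd pointer-noise jitter applied to trajectory points
#'   (mm).
#' @param seed master seed; every random draw derives from it.
#' @return object of class `virtual_study`: `table` (one row per fit:
#'   subject, strategy, walk, n_steps, trajectory length and geodesic
#'   length, coverage, RMSEs of the joint fit and both benchmarks,
#'   iterations, convergence), `model`, `failures` count.
#' @export
run_virtual_study <- function(n_subjects = 20L, n_walks_per_subject = 5L,
                              strategies = "side_to_top",
                              n_steps_range = 1:16,
                              spec = population_spec(),
                              n_train = 100L,
                              config = fit_config(),
                              sample_noise_sd = 0,
                              seed = 1L) {
  template <- make_template_head(resolution = spec$template_resolution)
  truth <- true_model(template, spec$n_modes, spec$mode_amplitudes)
  train_spec <- spec
  train_spec$n_subjects <- as.integer(n_train)
  train_spec$seed <- spec$seed + 1000L
  pop <- make_population(template, train_spec)
  model <- build_from_meshes(pop$meshes,
                             landmarks = attr(template, "landmarks"),
                             frame = attr(template, "frame"))
  k <- min(spec$n_modes, config$num_components, model$k)
  model <- truncate_model(model, k)
  rows <- list()
  failures <- 0L
  with_seed(seed, {
    for (si in seq_len(n_subjects)) {
      w_true <- rnorm(spec$n_modes)
      pose_true <- head_pose(scale = exp(runif(3, log(0.96), log(1.04))),
                             rotation = runif(3, -0.09, 0.09),
                             translation = runif(3, -20, 20))
      subj <- make_subject(truth, w_true, pose_true)
      gt <- subj$mesh
      frame <- subj$meta$frame
      graph <- build_edge_graph(gt)
      lm3_t <- model_landmarks(model, 3)
      lm7_t <- model_landmarks(model, 7)
      lm3_s <- subject_landmarks(gt, model, frame, 3)
      lm7_s <- subject_landmarks(gt, model, frame, 7)
      bench3 <- landmark_register(lm3_t, lm3_s, model)
      bench7 <- landmark_register(lm7_t, lm7_s, model)
      rmse_b3 <- position_rmse(gt, bench3$mesh)
      rmse_b7 <- position_rmse(gt, bench7$mesh)
      for (strat in strategies) {
        for (wi in seq_len(n_walks_per_subject)) {
          n_steps <- n_steps_range[sample.int(length(n_steps_range), 1)]
          walk_seed <- sample.int(.Machine$integer.max, 1)
          row <- tryCatch({
            sections <- partition_sections(gt, graph, n_steps, frame)
            traj <- sample_strategy(gt, graph, sections, strat, n_steps,
                                    seed = walk_seed)
            pts <- traj$points
            if (sample_noise_sd > 0)
              pts <- pts + matrix(rnorm(length(pts), sd = sample_noise_sd),
                                  nrow(pts))
            fit <- fit_scalp(model, pts, config = config)
            data.frame(subject = si, strategy = strat, walk = wi,
                       n_steps = n_steps,
                       length_mm = traj$length,
                       geodesic_mm = traj$geodesic_length,
                       coverage = surface_coverage(traj, gt, radius = 5),
                       rmse_fit = position_rmse(gt, fit$reconstructed),
                       rmse_bench3 = rmse_b3, rmse_bench7 = rmse_b7,
                       iterations = fit$iterations_run,
                       converged = fit$converged)
          }, error = function(e) {
            warning("subject ", si, " walk ", wi, " failed: ",
                    conditionMessage(e))
            NULL
          })
          if (is.null(row)) failures <- failures + 1L
          else rows[[length(rows) + 1L]] <- row
        }
      }
    }
  })
  structure(list(table = do.call(rbind, rows), model = model,
                 failures = failures, seed = seed),
            class = "virtual_study")
}

#' @export
print.virtual_study <- function(x, ...) {
  tb <- x$table
  cat(sprintf("virtual study: %d fits (%d failures)\n", nrow(tb), x$failures))
  for (s in unique(tb$strategy)) {
    sel <- tb$strategy == s
    cat(sprintf("  %-16s mean RMSE %.2f mm (benchmarks %.2f / %.2f mm)\n",
                s, mean(tb$rmse_fit[sel]), mean(tb$rmse_bench3[sel]),
                mean(tb$rmse_bench7[sel])))
  }
  invisible(x)
}
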