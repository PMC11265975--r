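#' Optimization settings for the joint fit
#'
#' Defaults follow the settings used throughout the virtual and lab studies:
#' loss-term coefficients `lambda1 = 10` (Chamfer), `lambda2 = 1` (normal
#' consistency), `lambda3 = 1` (weight Frobenius penalty), `lambda4 = 1`
#' (transform deviation penalty), an Adam optimizer with learning rate
#' `1e-3`, at most 1000 iterations with early stopping, 50 model
#' components, and spatial distances measured in centimeters inside the
#' loss (mesh coordinates remain in millimeters at the interface).
#'
#' @param lambda1,lambda2,lambda3,lambda4 non-negative loss coefficients.
#' @param learning_rate Adam step size.
#' @param max_iter iteration budget.
#' @param patience early stopping: iterations without a `min_delta` loss
#'   improvement before the fit is declared converged.
#' @param min_delta minimum loss improvement (loss units).
#' @param num_components leading model components optimized.
#' @param use_normals include the normal-consistency term.
#' @param squared use squared Euclidean distances in the Chamfer term
#'   (`FALSE` gives plain Euclidean distances).
#' @param correspondence `"surface"` (default) pairs each sample with its
#'   exact closest point on the reconstructed triangle surface (barycentric
#'   correspondence); `"vertex"` pairs with the closest vertex, as in a
#'   point-to-point Chamfer distance. At the vertex densities this package
#'   works with, vertex correspondence floors the attainable accuracy at
#'   about half the mesh edge length; surface correspondence removes that
#'   discretization floor and is identical in the dense-mesh limit.
#' @param distance_units `"cm"` or `"mm"`: units in which the loss (and its
#'   coefficients) operate.
#' @param seed reserved for stochastic extensions; the fit itself is
#'   deterministic given its inputs.
#' @return a list of class `fit_config`.
#' @export
fit_config <- function(lambda1 = 10, lambda2 = 1, lambda3 = 1, lambda4 = 1,
                       learning_rate = 1e-3, max_iter = 1000L,
                       patience = 50L, min_delta = 1e-6,
                       num_components = 50L, use_normals = FALSE,
                       squared = TRUE, correspondence = c("surface", "vertex"),
                       distance_units = c("cm", "mm"), seed = NULL) {
  distance_units <- match.arg(distance_units)
  correspondence <- match.arg(correspondence)
  if (any(c(lambda1, lambda2, lambda3, lambda4) < 0))
    stop("loss coefficients must be non-negative")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 lambda4 = lambda4, learning_rate = learning_rate,
                 max_iter = as.integer(max_iter),
                 patience = as.integer(patience), min_delta = min_delta,
                 num_components = as.integer(num_components),
                 use_normals = use_normals, squared = squared,
                 correspondence = correspondence,
                 distance_units = distance_units, seed = seed),
            class = "fit_config")
}

#' One-sided Chamfer distance
#'
#' Mean nearest-neighbor distance from each sampled point to the target
#' cloud; distances originate only in the samples, which keeps the measure
#' meaningful when a sparse trajectory is compared against a dense surface.
#' Squared Euclidean distances by default, plain Euclidean optionally.
#'
#' @param sampled,target point sets.
#' @param squared use squared distances.
#' @return list with `cd`, the `correspondences` (target index per sample)
#'   and the Euclidean `distances`.
#' @export
one_sided_chamfer <- function(sampled, target, squared = TRUE) {
  nn <- nearest_neighbors(sampled, target)
  cd <- if (squared) mean(nn$distance^2) else mean(nn$distance)
  list(cd = cd, correspondences = nn$index, distances = nn$distance)
}

#' Normal-consistency distance
#'
#' `mean(1 - |cos angle|)` between paired normals; the absolute value makes
#' the measure invariant to normal sign, since estimated sample normals have
#' no reliable inward/outward guarantee. Lies in [0, 1].
#'
#' @param sampled_normals,target_normals q x 3 matrices of paired normals.
#' @return the mean inconsistency.
#' @export
normal_consistency <- function(sampled_normals, target_normals) {
  a <- as.matrix(sampled_normals)
  b <- as.matrix(target_normals)
  if (!all(dim(a) == dim(b))) stop("normal sets must be paired")
  na <- sqrt(rowSums(a^2))
  nb <- sqrt(rowSums(b^2))
  if (any(na == 0) || any(nb == 0)) stop("zero-norm normal")
  mean(1 - abs(rowSums(a * b) / (na * nb)))
}

#' Regularized total loss
#'
#' `loss = lambda1 * cd + lambda2 * cn + reg` with
#' `reg = lambda3 * ||w||_F + lambda4 * ||T - T0||_F`, the last term taken
#' on the 4 x 4 homogeneous pose matrices.
#'
#' @param cd,cn Chamfer and normal-consistency terms.
#' @param weights current shape weights.
#' @param pose,pose0 current and initialization [head_pose()] (in the units
#'   the loss operates in).
#' @param config a [fit_config()].
#' @return list with `loss` and `reg`.
#' @export
total_loss <- function(cd, cn, weights, pose, pose0, config) {
  reg <- config$lambda3 * sqrt(sum(weights^2)) +
    config$lambda4 * pose_matrix_dist(pose, pose0)
  list(loss = config$lambda1 * cd + config$lambda2 * cn + reg, reg = reg)
}

#' Coarse alignment of the model to the samples
#'
#' Annotation-free initialization from the samples' coarse shape. Two
#' families of candidates are formed: (i) principal-axis alignment — the
#' translation matches centroids, the per-axis scale matches
#' principal-axis extents, and the rotation aligns the principal axes of
#' the samples with those of the model mean, under all four
#' proper-rotation sign assignments — and (ii) a rotation-free sphere
#' candidate — a least-squares sphere fit to the samples supplies the head
#' center and an isotropic radius-ratio scale, with identity rotation.
#' The principal-axis family is reliable when the samples surround the
#' head (dense or near-complete clouds); the sphere candidate is the sound
#' estimate for partial shells such as a single sampling sweep, whose
#' principal axes bear no relation to the head's. The candidate with the
#' lowest one-sided Chamfer distance is returned. Degenerate sample
#' spreads (rank < 3) fall back to the sphere candidate alone, flagged via
#' the `degenerate` attribute.
#'
#' @param sampled point set (>= 10 points), same units as the model.
#' @param model a [morphable_model()].
#' @param all_candidates return every proper-rotation candidate (ordered by
#'   Chamfer distance, best first) instead of only the winner — the basis
#'   of the multi-start option of [fit_scalp()].
#' @return a [head_pose()] mapping the model mean towards the samples (or a
#'   list of candidate poses).
#' @export
coarse_init <- function(sampled, model, all_candidates = FALSE) {
  pts <- as_points(sampled)
  if (nrow(pts) < 10L) stop("coarse initialization needs >= 10 points")
  mv <- model$mean$vertices
  cs <- colMeans(pts)
  cm <- colMeans(mv)
  Zs <- sweep(pts, 2, cs)
  Zm <- sweep(mv, 2, cm)
  # rotation-free sphere candidate: head center and radius from a linear
  # least-squares sphere fit
  sph_s <- sphere_fit(pts)
  sph_m <- sphere_fit(mv)
  s_iso <- if (sph_s$radius > 0 && sph_m$radius > 0)
    sph_s$radius / sph_m$radius else 1
  sphere_cand <- head_pose(scale = rep(s_iso, 3), rotation = c(0, 0, 0),
                           translation = sph_s$center - s_iso * sph_m$center)
  attr(sphere_cand, "degenerate") <- FALSE
  attr(sphere_cand, "cd") <-
    one_sided_chamfer(pts, apply_pose(sphere_cand, mv))$cd
  es <- eigen(crossprod(Zs) / nrow(Zs), symmetric = TRUE)
  em <- eigen(crossprod(Zm) / nrow(Zm), symmetric = TRUE)
  if (es$values[3] < 1e-8 * es$values[1]) {
    pose <- sphere_cand
    attr(pose, "degenerate") <- TRUE
    return(if (all_candidates) list(pose) else pose)
  }
  As <- es$vectors
  Am <- em$vectors
  if (det(As) < 0) As[, 3] <- -As[, 3]
  if (det(Am) < 0) Am[, 3] <- -Am[, 3]
  signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  cands <- lapply(signs, function(sg) {
    R <- As %*% diag(sg) %*% t(Am)
    Y <- Zs %*% R  # samples expressed in the model frame
    s <- apply(Y, 2, sd) / pmax(apply(Zm, 2, sd), 1e-12)
    s <- pmax(s, 1e-3)
    t <- cs - drop(R %*% (s * cm))
    cand <- head_pose(scale = s, rotation = axis_angle(R), translation = t)
    attr(cand, "degenerate") <- FALSE
    attr(cand, "cd") <- one_sided_chamfer(pts, apply_pose(cand, mv))$cd
    cand
  })
  cands <- c(cands, list(sphere_cand))
  cands <- cands[order(vapply(cands, attr, 0, "cd"))]
  if (all_candidates) cands else cands[[1]]
}

# Least-squares sphere through a point set: ||x||^2 = 2 c.x + (r^2 - c.c)
# is linear in (c, r^2 - c.c).
sphere_fit <- function(p) {
  A <- cbind(2 * p, 1)
  beta <- tryCatch(qr.solve(A, rowSums(p^2)), error = function(e) NULL)
  if (is.null(beta)) {
    ctr <- colMeans(p)
    return(list(center = ctr,
                radius = sqrt(mean(rowSums(sweep(p, 2, ctr)^2)))))
  }
  ctr <- beta[1:3]
  r2 <- beta[4] + sum(ctr^2)
  list(center = ctr, radius = sqrt(max(r2, 0)))
}

# Vertex -> incident-face adjacency in CSR form (1-based) for the
# closest-surface queries.
vertex_face_csr <- function(faces, n) {
  vid <- as.vector(faces)
  fid <- rep(seq_len(nrow(faces)), 3L)
  o <- order(vid, fid)
  list(ptr = as.integer(cumsum(c(1L, tabulate(vid, n)))),
       idx = as.integer(fid[o]))
}

#' Exact point-to-surface distances
#'
#' Distance from each query point to the closest point on a triangle mesh
#' surface (not just its vertices), found by exact closest-point-on-triangle
#' tests.
#'
#' @param points q x 3 coordinates.
#' @param mesh a [trimesh()].
#' @return list with `distance`, the supporting `face` index and the
#'   barycentric coordinates `bary` of each closest point.
#' @export
point_to_surface_distance <- function(points, mesh) {
  stopifnot(inherits(mesh, "trimesh"))
  pts <- as_points(points)
  vf <- vertex_face_csr(mesh$faces, nrow(mesh$vertices))
  .closest_surface(pts, mesh$vertices, mesh$faces, vf$ptr, vf$idx)
}

# Vertex normals without the full trimesh machinery (inner-loop use).
vnormals_quick <- function(v, f) {
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n <- matrix(0, nrow(v), 3)
  for (j in 1:3) {
    s <- rowsum(fn, f[, j])
    idx <- as.integer(rownames(s))
    n[idx, ] <- n[idx, ] + s
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  ctr <- colMeans(v)
  if (sum(rowSums(n * sweep(v, 2, ctr)) < 0) > nrow(v) / 2) n <- -n
  n
}

# Adam loop over the regularized objective. Correspondences refresh every
# iteration; early stopping after `patience` iterations without a
# `min_delta` improvement. Returns the final parameters, the per-iteration
# loss terms, and the best loss seen.
run_adam <- function(par, data, config, max_iter = config$max_iter) {
  m <- v <- numeric(length(par))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  hist_cd <- hist_cn <- hist_reg <- hist_total <- numeric(max_iter)
  best <- Inf
  wait <- 0L
  converged <- FALSE
  iters <- 0L
  for (i in seq_len(max_iter)) {
    lg <- loss_and_grad(par, data)
    if (!is.finite(lg$loss))
      stop("non-finite loss at iteration ", i,
           " (cd = ", signif(lg$cd, 4), ", reg = ", signif(lg$reg, 4), ")")
    iters <- i
    hist_cd[i] <- lg$cd; hist_cn[i] <- lg$cn
    hist_reg[i] <- lg$reg; hist_total[i] <- lg$loss
    if (lg$loss < best - config$min_delta) {
      best <- lg$loss
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) { converged <- TRUE; break }
    }
    g <- lg$grad
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    par <- par - lr * (m / (1 - b1^i)) / (sqrt(v / (1 - b2^i)) + eps)
  }
  list(par = par, iters = iters, converged = converged, best_loss = best,
       history = data.frame(iteration = seq_len(iters),
                            cd = hist_cd[seq_len(iters)],
                            cn = hist_cn[seq_len(iters)],
                            reg = hist_reg[seq_len(iters)],
                            total = hist_total[seq_len(iters)]))
}

# Parameter vector layout: [w (k), log scale (3), axis-angle (3), t (3)].
unpack_par <- function(par, k) {
  list(w = par[seq_len(k)], logs = par[k + 1:3], rot = par[k + 4:6],
       t = par[k + 7:9])
}

# Loss and analytic gradient of the regularized objective. When `corr`
# (correspondences) is NULL they are recomputed from the current shape, as
# in each outer iteration; passing fixed `corr`/`n0` makes the function a
# smooth deterministic objective suitable for finite-difference checks.
# In surface mode `corr` is the closest-triangle structure (face +
# barycentric weights); in vertex mode it is the nearest-vertex index
# vector. All quantities are in the loss units (data prepared by
# fit_scalp).
loss_and_grad <- function(par, data, corr = NULL, n0 = NULL) {
  cfg <- data$config
  k <- data$k
  p <- unpack_par(par, k)
  s <- exp(p$logs)
  R <- rotation_matrix(p$rot)
  verts <- data$mu
  if (k > 0 && any(p$w != 0))
    verts <- verts + unflatten_vertices(data$V %*% (p$w * data$e))
  P <- sweep(verts, 2, s, "*") %*% t(R) +
    matrix(p$t, nrow(verts), 3, byrow = TRUE)
  q <- nrow(data$X)
  surface_mode <- identical(cfg$correspondence, "surface")
  if (surface_mode) {
    if (is.null(corr))
      corr <- .closest_surface(data$X, P, data$faces, data$vf_ptr,
                               data$vf_idx)
    fv <- data$faces[corr$face, , drop = FALSE]
    r <- corr$bary[, 1] * P[fv[, 1], , drop = FALSE] +
      corr$bary[, 2] * P[fv[, 2], , drop = FALSE] +
      corr$bary[, 3] * P[fv[, 3], , drop = FALSE]
    E <- r - data$X
  } else {
    if (is.null(corr)) corr <- .nn_brute(data$X, P)$index
    E <- P[corr, , drop = FALSE] - data$X
  }
  d2 <- rowSums(E^2)
  if (cfg$squared) {
    cd <- mean(d2)
    Gd <- (2 / q) * E
  } else {
    d <- sqrt(pmax(d2, 1e-300))
    cd <- mean(d)
    Gd <- (1 / q) * E / d
  }
  G <- cfg$lambda1 * Gd
  if (surface_mode) {
    # scatter each sample's gradient onto the three face vertices
    cor3 <- as.vector(fv)
    G <- G[rep(seq_len(q), 3L), , drop = FALSE] * as.vector(corr$bary)
  } else {
    cor3 <- corr
  }
  gt <- colSums(G)
  B <- G %*% R
  vc <- verts[cor3, , drop = FALSE]
  glogs <- colSums(B * vc) * s
  dR <- rotation_matrix_grad(p$rot)
  U <- sweep(vc, 2, s, "*")
  grot <- vapply(dR, function(D) sum((G %*% D) * U), 0)
  gw <- numeric(k)
  if (k > 0) {
    Bs <- sweep(B, 2, s, "*")
    ridx <- as.vector(rbind(3L * (cor3 - 1L) + 1L,
                            3L * (cor3 - 1L) + 2L,
                            3L * (cor3 - 1L) + 3L))
    gw <- data$e * drop(crossprod(data$V[ridx, , drop = FALSE],
                                  as.vector(t(Bs))))
  }
  cn <- 0
  if (cfg$use_normals && !is.null(data$Xn)) {
    if (is.null(n0)) n0 <- vnormals_quick(verts, data$faces)
    n0c <- if (surface_mode) {
      corr$bary[, 1] * n0[fv[, 1], , drop = FALSE] +
        corr$bary[, 2] * n0[fv[, 2], , drop = FALSE] +
        corr$bary[, 3] * n0[fv[, 3], , drop = FALSE]
    } else n0[corr, , drop = FALSE]
    A <- sweep(n0c, 2, s, "/") %*% t(R)
    an <- pmax(sqrt(rowSums(A^2)), 1e-12)
    m <- A / an
    cosv <- rowSums(data$Xn * m)
    cn <- mean(1 - abs(cosv))
    dfdm <- -(sign(cosv) / q) * data$Xn
    W <- cfg$lambda2 * (dfdm - m * rowSums(m * dfdm)) / an
    WR <- W %*% R
    glogs <- glogs - colSums(WR * n0c) / s  # via d(1/s_a)/dlog s_a = -1/s_a
    n0s <- sweep(n0c, 2, s, "/")
    grot <- grot + vapply(dR, function(D) sum((W %*% D) * n0s), 0)
  }
  nw <- sqrt(sum(p$w^2))
  Tm <- diag(4)
  Tm[1:3, 1:3] <- R %*% diag(s)
  Tm[1:3, 4] <- p$t
  DT <- Tm - data$T0
  ndt <- sqrt(sum(DT^2))
  reg <- cfg$lambda3 * nw + cfg$lambda4 * ndt
  if (cfg$lambda3 > 0 && nw > 1e-12) gw <- gw + cfg$lambda3 * p$w / nw
  if (cfg$lambda4 > 0 && ndt > 1e-12) {
    M <- DT[1:3, 1:3] / ndt
    glogs <- glogs + cfg$lambda4 * colSums(M * R) * s
    grot <- grot + cfg$lambda4 *
      vapply(dR, function(D) sum(M * (D %*% diag(s))), 0)
    gt <- gt + cfg$lambda4 * DT[1:3, 4] / ndt
  }
  loss <- cfg$lambda1 * cd + cfg$lambda2 * cn + reg
  list(loss = loss, cd = cd, cn = cn, reg = reg,
       grad = c(gw, glogs, grot, gt), corr = corr)
}

#' Jointly fit pose and shape-model weights to sparse surface samples
#'
#' The central estimator: starting from a coarse (or supplied)
#' initialization, the non-uniform similarity transform and the shape-model
#' weights are optimized simultaneously by Adam against the regularized
#' one-sided Chamfer objective ([total_loss()]). Correspondences are
#' recomputed at every iteration; the scale is parameterized on the log
#' scale (so it can never be driven non-positive) and the rotation as an
#' axis-angle vector, leaving the problem unconstrained. Early stopping
#' triggers when the loss fails to improve by `min_delta` for `patience`
#' consecutive iterations.
#'
#' @param model a [morphable_model()] (truncated internally to
#'   `config$num_components`).
#' @param sampled sparse samples: a `trajectory`, [point_cloud()] or q x 3
#'   matrix in millimeters. Sample normals (required when
#'   `config$use_normals`) are taken from the object or `sample_normals`.
#' @param pose0 optional initialization [head_pose()] in millimeters;
#'   computed by [coarse_init()] when omitted.
#' @param config a [fit_config()].
#' @param sample_normals optional q x 3 unit normals for the samples.
#' @param multi_start try every proper-rotation coarse-initialization
#'   candidate with a short trial optimization and continue from the best,
#'   instead of trusting the candidate with the lowest initial Chamfer
#'   distance (the default). Guards against flipped principal-axis
#'   assignments on subjects whose shape reverses the template's
#'   asymmetries; costs about four trial runs of `multi_start_iters`
#'   iterations. Ignored when `pose0` is supplied.
#' @param multi_start_iters trial budget per candidate.
#' @return an object of class `scalp_fit` with components `weights`, `pose`
#'   (millimeters), `pose0`, `reconstructed` (the posed synthesized
#'   [trimesh()], mm), `loss_history` (per-iteration cd, cn, reg, total),
#'   `iterations_run`, `converged`, plus the config and inputs needed by
#'   the methods ([residuals.scalp_fit()], [summary.scalp_fit()], ...).
#' @seealso [coarse_init()], [fit_config()], [position_rmse()]
#' @export
fit_scalp <- function(model, sampled, pose0 = NULL, config = fit_config(),
                      sample_normals = NULL, multi_start = TRUE,
                      multi_start_iters = 150L) {
  stopifnot(inherits(model, "morphable_model"), inherits(config, "fit_config"))
  pts <- if (inherits(sampled, "trajectory")) sampled$points
         else as_points(sampled)
  if (is.null(sample_normals) && inherits(sampled, "trajectory"))
    sample_normals <- sampled$normals
  if (is.null(sample_normals) && inherits(sampled, "point_cloud"))
    sample_normals <- sampled$normals
  if (config$use_normals && is.null(sample_normals))
    stop("config$use_normals is TRUE but no sample normals are available")
  k <- min(model$k, config$num_components)
  model_k <- if (k < model$k) truncate_model(model, k) else model
  u <- if (config$distance_units == "cm") 0.1 else 1
  vf <- vertex_face_csr(model_k$mean$faces, nrow(model_k$mean$vertices))
  data <- list(
    X = pts * u,
    Xn = sample_normals,
    mu = model_k$mean$vertices * u,
    V = model_k$eigenvectors,
    e = model_k$eigenvalues * u,
    faces = model_k$mean$faces,
    vf_ptr = vf$ptr, vf_idx = vf$idx,
    T0 = diag(4),
    k = k,
    config = config)
  prepare <- function(p0) {
    p0u <- head_pose(scale = p0$scale, rotation = p0$rotation,
                     translation = p0$translation * u)
    list(T0 = pose_matrix(p0u),
         par = c(numeric(k), log(p0u$scale), p0u$rotation, p0u$translation))
  }
  if (is.null(pose0)) {
    if (multi_start) {
      cands <- coarse_init(pts, model_k, all_candidates = TRUE)
      # trial-optimize only candidates whose initial Chamfer distance is
      # competitive (within 3x RMS of the best)
      cds <- vapply(cands, attr, 0, "cd")
      cands <- cands[cds <= 9 * min(cds) + 1e-12]
      if (length(cands) > 1L) {
        trial_loss <- vapply(cands, function(p0) {
          init <- prepare(p0)
          data$T0 <- init$T0
          run_adam(init$par, data, config,
                   max_iter = multi_start_iters)$best_loss
        }, 0)
        pose0 <- cands[[which.min(trial_loss)]]
      } else pose0 <- cands[[1]]
    } else pose0 <- coarse_init(pts, model_k)
  }
  init <- prepare(pose0)
  data$T0 <- init$T0
  opt <- run_adam(init$par, data, config)
  iters <- opt$iters
  converged <- opt$converged
  p <- unpack_par(opt$par, k)
  pose <- head_pose(scale = exp(p$logs), rotation = p$rot,
                    translation = p$t / u)
  reconstructed <- apply_pose(pose, synthesize(model_k, p$w))
  structure(list(
    weights = p$w, pose = pose, pose0 = pose0,
    reconstructed = reconstructed,
    loss_history = opt$history,
    iterations_run = iters, converged = converged,
    config = config, k = k, chamfer = if (config$squared) "squared"
                                      else "euclidean",
    sampled_points = pts, sample_normals = sample_normals,
    call = match.call()),
    class = "scalp_fit")
}

#' @export
print.scalp_fit <- function(x, ...) {
  cat("Joint scalp-surface fit\n")
  cat(sprintf("  %d samples, %d model components, %s Chamfer (%s)\n",
              nrow(x$sampled_points), x$k, x$chamfer,
              x$config$distance_units))
  cat(sprintf("  %d iterations (%s), final loss %.6g\n", x$iterations_run,
              if (x$converged) "early stopping" else "budget exhausted",
              tail(x$loss_history$total, 1)))
  print(x$pose)
  invisible(x)
}

#' @export
coef.scalp_fit <- function(object, ...) object$weights

#' @export
fitted.scalp_fit <- function(object, ...) object$reconstructed

#' Residual sample-to-surface distances
#'
#' Euclidean distance (mm) from each input sample to the reconstructed
#' surface, measured the way the fit measured it (closest surface point,
#' or closest vertex for `correspondence = "vertex"`).
#'
#' @param object a `scalp_fit`.
#' @param ... unused.
#' @export
residuals.scalp_fit <- function(object, ...) {
  if (identical(object$config$correspondence, "surface"))
    point_to_surface_distance(object$sampled_points,
                              object$reconstructed)$distance
  else
    nearest_neighbors(object$sampled_points,
                      object$reconstructed$vertices)$distance
}

#' Nearest reconstructed-surface points for new samples
#'
#' @param object a `scalp_fit`.
#' @param newdata optional q x 3 points (mm); defaults to the fitted
#'   samples.
#' @param ... unused.
#' @return matrix of the nearest reconstructed vertices with attribute
#'   `distance`.
#' @export
predict.scalp_fit <- function(object, newdata = NULL, ...) {
  pts <- if (is.null(newdata)) object$sampled_points else as_points(newdata)
  nn <- nearest_neighbors(pts, object$reconstructed$vertices)
  out <- object$reconstructed$vertices[nn$index, , drop = FALSE]
  attr(out, "distance") <- nn$distance
  out
}

#' @export
summary.scalp_fit <- function(object, ...) {
  r <- residuals(object)
  structure(list(
    n_samples = nrow(object$sampled_points), k = object$k,
    iterations_run = object$iterations_run, converged = object$converged,
    final = tail(object$loss_history, 1),
    residual_rmse = sqrt(mean(r^2)), residual_max = max(r),
    weight_norm = sqrt(sum(object$weights^2)),
    pose = object$pose), class = "summary.scalp_fit")
}

#' @export
print.summary.scalp_fit <- function(x, ...) {
  cat("Joint scalp-surface fit\n")
  cat(sprintf("  samples: %d   components: %d   iterations: %d (%s)\n",
              x$n_samples, x$k, x$iterations_run,
              if (x$converged) "converged" else "max_iter"))
  cat(sprintf("  final loss %.6g  (cd %.6g, cn %.6g, reg %.6g)\n",
              x$final$total, x$final$cd, x$final$cn, x$final$reg))
  cat(sprintf("  sample residuals: RMSE %.3f mm, max %.3f mm\n",
              x$residual_rmse, x$residual_max))
  cat(sprintf("  ||w||_F = %.3f\n", x$weight_norm))
  print(x$pose)
  invisible(x)
}

#' Loss-history plot for a joint fit
#'
#' @param x a `scalp_fit`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.scalp_fit <- function(x, ...) {
  h <- x$loss_history
  graphics::matplot(h$iteration, cbind(h$total, h$cd, h$reg), type = "l",
                    lty = 1, col = c("black", "steelblue", "tomato"),
                    xlab = "iteration", ylab = "loss terms", log = "y", ...)
  graphics::legend("topright", c("total", "cd", "reg"), lty = 1,
                   col = c("black", "steelblue", "tomato"), bty = "n")
  invisible(x)
}
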