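#' Linear statistical shape model (3D morphable model)
#'
#' A 3DMM consists of a mean mesh, unit-norm eigenvectors in dense vertex
#' correspondence with it, and per-mode eigenvalues. Shape instances are
#' `mean + sum_i w_i * e_i * v_i` ([synthesize()]). The eigenvalue `e_i` is
#' stored as the mode's standard deviation (the square root of the
#' covariance eigenvalue), so that weights `w_i` are standard-normal over
#' the training population and the Frobenius weight penalty acts in
#' standard-deviation units; imported models declare their own convention
#' in the container manifest.
#'
#' Eigenvectors are flattened vertex-major: entries `(x1, y1, z1, x2, ...)`.
#'
#' @param mean_mesh a [trimesh()] with n vertices.
#' @param eigenvalues positive, non-increasing vector of k mode SDs (same
#'   units as the vertices).
#' @param eigenvectors 3n x k matrix, unit-norm, mutually orthogonal columns.
#' @param landmarks optional named integer vector of landmark vertex indices
#'   on the mean mesh (e.g. nasion, lpa, rpa).
#' @param frame optional [head_frame()] of the mean mesh.
#' @param validate check invariants.
#' @return an object of class `morphable_model`.
#' @export
morphable_model <- function(mean_mesh, eigenvalues, eigenvectors,
                            landmarks = NULL, frame = NULL, validate = TRUE) {
  stopifnot(inherits(mean_mesh, "trimesh"))
  eigenvalues <- as.numeric(eigenvalues)
  eigenvectors <- as.matrix(eigenvectors)
  n <- nrow(mean_mesh$vertices)
  k <- length(eigenvalues)
  if (validate) {
    if (ncol(eigenvectors) != k) stop("eigenvector/eigenvalue count mismatch")
    if (nrow(eigenvectors) != 3L * n) stop("eigenvectors must be 3n x k")
    if (k > 0) {
      if (any(eigenvalues <= 0)) stop("eigenvalues must be positive")
      if (any(diff(eigenvalues) > 1e-12)) stop("eigenvalues must be non-increasing")
      norms <- sqrt(colSums(eigenvectors^2))
      if (any(abs(norms - 1) > 1e-9)) stop("eigenvectors must have unit norm")
      gram <- crossprod(eigenvectors)
      if (max(abs(gram - diag(k))) > 1e-6)
        stop("eigenvectors must be mutually orthogonal")
    }
  }
  structure(list(mean = mean_mesh, eigenvalues = eigenvalues,
                 eigenvectors = eigenvectors, n_vertices = n, k = k,
                 landmarks = landmarks, frame = frame),
            class = "morphable_model")
}

#' @export
print.morphable_model <- function(x, ...) {
  cat(sprintf("morphable_model: %d vertices, %d components\n",
              x$n_vertices, x$k))
  if (x$k > 0)
    cat(sprintf("  mode SDs: %s%s\n",
                paste(signif(head(x$eigenvalues, 5), 4), collapse = ", "),
                if (x$k > 5) ", ..." else ""))
  invisible(x)
}

#' Synthesize a shape instance from model weights
#'
#' Computes `mean + sum_i w_i * e_i * v_i`, reshaped to n x 3; the face
#' topology is copied from the mean mesh. A short weight vector is padded
#' with zeros.
#'
#' @param model a [morphable_model()].
#' @param w numeric weights, `length(w) <= k`.
#' @return a [trimesh()].
#' @export
synthesize <- function(model, w) {
  stopifnot(inherits(model, "morphable_model"))
  w <- as.numeric(w)
  if (length(w) > model$k) stop("more weights than model components")
  if (length(w) < model$k) w <- c(w, numeric(model$k - length(w)))
  v <- model$mean$vertices
  if (model$k > 0 && any(w != 0)) {
    delta <- model$eigenvectors %*% (w * model$eigenvalues)
    v <- v + matrix(delta, ncol = 3, byrow = TRUE)
  }
  trimesh(v, model$mean$faces, validate = FALSE)
}

# Flatten an n x 3 vertex matrix vertex-major: (x1, y1, z1, x2, ...).
flatten_vertices <- function(v) as.vector(t(v))
unflatten_vertices <- function(x) matrix(x, ncol = 3, byrow = TRUE)

#' Build a morphable model by PCA over corresponded meshes
#'
#' All training meshes must share the vertex count and face topology (dense
#' correspondence). The mean is the vertex-wise average; modes come from the
#' SVD of the centered, flattened vertex matrix, equivalent to the
#' eigen-decomposition of the flattened-vertex covariance. Eigenvalues are
#' stored as mode standard deviations (see [morphable_model()]). Components
#' with an SD below `tol` times the leading SD are dropped. Eigenvector sign
#' is fixed by making the largest-magnitude entry positive, so rebuilt
#' models are deterministic up to training-set order.
#'
#' @param training list of [trimesh()] in correspondence (>= 2).
#' @param tol relative SD cutoff for dropping trailing components.
#' @param landmarks,frame forwarded to [morphable_model()].
#' @return a [morphable_model()].
#' @export
build_from_meshes <- function(training, tol = 1e-8, landmarks = NULL,
                              frame = NULL) {
  if (length(training) < 2L) stop("need at least two training meshes")
  f0 <- training[[1]]$faces
  n <- nrow(training[[1]]$vertices)
  for (m in training) {
    if (nrow(m$vertices) != n || !identical(unname(m$faces), unname(f0)))
      stop("training meshes must share vertex count and face topology")
  }
  X <- t(vapply(training, function(m) flatten_vertices(m$vertices),
                numeric(3L * n)))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0)
  sds <- sv$d / sqrt(nrow(X) - 1)
  keep <- which(sds > tol * sds[1] & sds > 0)
  V <- sv$v[, keep, drop = FALSE]
  sds <- sds[keep]
  # deterministic sign: largest-|entry| positive
  if (length(keep) > 0) {
    for (j in seq_len(ncol(V))) {
      i <- which.max(abs(V[, j]))
      if (V[i, j] < 0) V[, j] <- -V[, j]
    }
  }
  mean_mesh <- trimesh(unflatten_vertices(mu), f0, validate = FALSE)
  morphable_model(mean_mesh, sds, V, landmarks = landmarks, frame = frame)
}

#' Fraction of model variance captured by the leading components
#'
#' `sum(e_i, i <= k_used) / sum(e_i, i <= k)` over the stored eigenvalues —
#' the standard-deviation-based accounting used when choosing how many
#' components to optimize.
#'
#' @param model a [morphable_model()].
#' @param k_used number of leading components, `1 <= k_used <= k`.
#' @return a fraction in (0, 1].
#' @export
variance_fraction <- function(model, k_used) {
  stopifnot(inherits(model, "morphable_model"))
  if (k_used < 1 || k_used > model$k) stop("k_used out of range")
  sum(model$eigenvalues[seq_len(k_used)]) / sum(model$eigenvalues)
}

#' Truncate a model to its leading components
#'
#' @param model a [morphable_model()].
#' @param k_new number of components to retain.
#' @return a [morphable_model()] with the first `k_new` modes.
#' @export
truncate_model <- function(model, k_new) {
  stopifnot(inherits(model, "morphable_model"))
  if (k_new < 1 || k_new > model$k) stop("k_new out of range")
  morphable_model(model$mean, model$eigenvalues[seq_len(k_new)],
                  model$eigenvectors[, seq_len(k_new), drop = FALSE],
                  landmarks = model$landmarks, frame = model$frame,
                  validate = FALSE)
}

#' Project a corresponded mesh onto the model modes
#'
#' Least-squares weights reproducing `mesh` from the model:
#' `w_i = <flat(mesh) - flat(mean), v_i> / e_i`.
#'
#' @param model a [morphable_model()].
#' @param mesh a [trimesh()] in correspondence with the mean.
#' @return numeric weight vector of length k.
#' @export
project_onto_model <- function(model, mesh) {
  stopifnot(inherits(model, "morphable_model"), inherits(mesh, "trimesh"))
  d <- flatten_vertices(mesh$vertices) - flatten_vertices(model$mean$vertices)
  drop(crossprod(model$eigenvectors, d)) / model$eigenvalues
}

#' Save / load a morphable model container
#'
#' The container is a directory holding `mean.ply` (ASCII), plain-text
#' matrices `eigenvectors.txt` (3n x k, vertex-major rows) and
#' `eigenvalues.txt`, and a `manifest.json` recording `n_vertices`, `k`,
#' coordinate `units`, the `eigenvalue_convention` (`"sd"` for models built
#' here) and optional landmark vertex indices and head frame. Externally
#' supplied models with the same layout can be dropped in.
#'
#' @param model a [morphable_model()].
#' @param dir container directory (created if missing).
#' @param units coordinate units recorded in the manifest.
#' @return `dir` (saver) or a [morphable_model()] (loader).
#' @export
save_model <- function(model, dir, units = "mm") {
  stopifnot(inherits(model, "morphable_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ply(model$mean, file.path(dir, "mean.ply"))
  write.table(model$eigenvectors, file.path(dir, "eigenvectors.txt"),
              row.names = FALSE, col.names = FALSE)
  writeLines(format(model$eigenvalues, digits = 17, scientific = TRUE),
             file.path(dir, "eigenvalues.txt"))
  manifest <- list(n_vertices = model$n_vertices, k = model$k, units = units,
                   eigenvalue_convention = "sd")
  if (!is.null(model$landmarks)) manifest$landmarks <- as.list(model$landmarks)
  if (!is.null(model$frame)) manifest$frame <- unclass(model$frame)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  mean_mesh <- read_ply(file.path(dir, "mean.ply"))
  V <- as.matrix(read.table(file.path(dir, "eigenvectors.txt")))
  dimnames(V) <- NULL
  e <- as.numeric(readLines(file.path(dir, "eigenvalues.txt")))
  landmarks <- if (!is.null(manifest$landmarks))
    unlist(manifest$landmarks)
  frame <- if (!is.null(manifest$frame))
    head_frame(origin = manifest$frame$origin, front = manifest$frame$front,
               left = manifest$frame$left, up = manifest$frame$up)
  morphable_model(mean_mesh, e, V, landmarks = landmarks, frame = frame)
}
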