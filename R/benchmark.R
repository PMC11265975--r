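#' Landmark set
#'
#' A named set of fiducial coordinates. Three-landmark sets must be exactly
#' the conventional fiducials (nasion and left/right preauricular points);
#' larger sets may add the four extremities (topmost, backmost, leftmost,
#' rightmost scalp points).
#'
#' @param names character labels from `nasion, lpa, rpa, topmost, backmost,
#'   leftmost, rightmost`.
#' @param coordinates length(names) x 3 matrix.
#' @param frame optional reference-frame tag.
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(names, coordinates, frame = NULL) {
  allowed <- c("nasion", "lpa", "rpa", "topmost", "backmost", "leftmost",
               "rightmost")
  names <- as.character(names)
  coordinates <- as.matrix(coordinates)
  if (length(names) < 3L) stop("need at least 3 landmarks")
  if (anyDuplicated(names)) stop("landmark names must be unique")
  if (!all(names %in% allowed))
    stop("unknown landmark name(s): ",
         paste(setdiff(names, allowed), collapse = ", "))
  if (length(names) == 3L && !setequal(names, c("nasion", "lpa", "rpa")))
    stop("a 3-landmark set must be exactly {nasion, lpa, rpa}")
  if (nrow(coordinates) != length(names) || ncol(coordinates) != 3L)
    stop("coordinates must be length(names) x 3")
  rownames(coordinates) <- names
  structure(list(names = names, coordinates = coordinates, frame = frame),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("landmark_set: %s\n", paste(x$names, collapse = ", ")))
  invisible(x)
}

#' Read / write landmark coordinates as CSV
#'
#' One row per landmark with columns `name,x,y,z`.
#'
#' @param path CSV path.
#' @return a [landmark_set()] (reader) or `path` invisibly (writer).
#' @export
read_landmarks_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "x", "y", "z") %in% names(df)))
    stop("landmark CSV needs name,x,y,z columns")
  landmark_set(df$name, unname(as.matrix(df[, c("x", "y", "z")])))
}

#' @rdname read_landmarks_csv
#' @param landmarks a [landmark_set()].
#' @export
write_landmarks_csv <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  df <- data.frame(name = landmarks$names,
                   x = landmarks$coordinates[, 1],
                   y = landmarks$coordinates[, 2],
                   z = landmarks$coordinates[, 3])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Extremity landmarks of a scalp mesh
#'
#' The topmost, backmost, leftmost and rightmost vertices with respect to a
#' declared head frame; ties are broken by the lowest vertex index.
#'
#' @param mesh a [trimesh()].
#' @param frame a [head_frame()].
#' @return a [landmark_set()] of the four extremities; attribute
#'   `vertex_ids` holds the source indices.
#' @export
pick_extremities <- function(mesh, frame) {
  stopifnot(inherits(mesh, "trimesh"), inherits(frame, "head_frame"))
  v <- mesh$vertices
  dirs <- rbind(topmost = frame$up, backmost = -frame$front,
                leftmost = frame$left, rightmost = -frame$left)
  ids <- apply(dirs, 1, function(d) which.max(drop(v %*% d)))
  out <- landmark_set(rownames(dirs), v[ids, , drop = FALSE], frame = "mesh")
  attr(out, "vertex_ids") <- ids
  out
}

# Umeyama closed-form least-squares similarity transform (rotation +
# isotropic scale + translation, reflections disallowed). `src`/`dst` are
# paired q x 3 point sets; returns list(R, s, t) with dst ~ s * R src + t.
umeyama <- function(src, dst, allow_scale = TRUE) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  n <- nrow(src)
  mu_s <- colMeans(src); mu_d <- colMeans(dst)
  Xs <- sweep(src, 2, mu_s); Xd <- sweep(dst, 2, mu_d)
  # rotation undefined for collinear/coincident landmark configurations
  spread <- svd(Xs, nu = 0, nv = 0)$d
  if (spread[2] < 1e-9 * max(spread[1], 1e-12))
    stop("degenerate (collinear or coincident) landmarks")
  S <- crossprod(Xd, Xs) / n
  sv <- svd(S)
  d <- diag(3)
  if (det(sv$u) * det(sv$v) < 0) d[3, 3] <- -1
  R <- sv$u %*% d %*% t(sv$v)
  var_s <- mean(rowSums(Xs^2))
  if (var_s < 1e-24) stop("degenerate (collinear or coincident) landmarks")
  s <- if (allow_scale) sum(diag(diag(sv$d) %*% d)) / var_s else 1
  t <- mu_d - s * drop(R %*% mu_s)
  list(R = R, s = s, t = t)
}

#' Landmark-based template registration (the benchmark method)
#'
#' Reproduces the conventional neuronavigation registration: a closed-form
#' least-squares similarity transform (rotation, isotropic scale,
#' translation; reflections disallowed) maps the template landmarks onto
#' the subject's, and the posed template mean mesh serves as the
#' reconstruction. An anisotropic-scale least-squares variant is available
#' for sensitivity analysis.
#'
#' @param template_landmarks,subject_landmarks [landmark_set()]s sharing
#'   names; the template set is matched onto the subject set.
#' @param model a [morphable_model()] supplying the template mean mesh.
#' @param anisotropic refine with a per-axis scale (least squares given the
#'   similarity rotation).
#' @return list with `pose` (a [head_pose()]), `mesh` (the posed template),
#'   and per-landmark `residuals` (mm).
#' @export
landmark_register <- function(template_landmarks, subject_landmarks, model,
                              anisotropic = FALSE) {
  stopifnot(inherits(template_landmarks, "landmark_set"),
            inherits(subject_landmarks, "landmark_set"),
            inherits(model, "morphable_model"))
  if (!setequal(template_landmarks$names, subject_landmarks$names))
    stop("landmark sets must share names")
  nm <- template_landmarks$names
  src <- template_landmarks$coordinates[nm, , drop = FALSE]
  dst <- subject_landmarks$coordinates[nm, , drop = FALSE]
  fit <- umeyama(src, dst, allow_scale = TRUE)
  scale <- rep(fit$s, 3)
  if (anisotropic) {
    # per-axis scale given the similarity rotation: regress rotated
    # centered source axes onto the centered destination
    mu_s <- colMeans(src); mu_d <- colMeans(dst)
    Xs <- sweep(src, 2, mu_s)
    Xd <- sweep(dst, 2, mu_d) %*% fit$R  # back-rotated
    scale <- vapply(1:3, function(a) {
      den <- sum(Xs[, a]^2)
      if (den < 1e-12) fit$s else sum(Xs[, a] * Xd[, a]) / den
    }, 0)
    scale <- pmax(scale, 1e-3)
  }
  t <- colMeans(dst) - drop(fit$R %*% (scale * colMeans(src)))
  pose <- head_pose(scale = scale, rotation = axis_angle(fit$R),
                    translation = t)
  res <- sqrt(rowSums((apply_pose(pose, src) - dst)^2))
  names(res) <- nm
  list(pose = pose, mesh = apply_pose(pose, model$mean), residuals = res)
}

#' Landmarks of a model's mean mesh
#'
#' Reads the fiducial landmark vertices annotated in the model container
#' (nasion, lpa, rpa) and, for a 7-landmark set, adds the extremities
#' picked from the mean mesh in the model's frame.
#'
#' @param model a [morphable_model()] with `landmarks` (and for
#'   `n_landmarks = 7`, a `frame`).
#' @param n_landmarks 3 or 7.
#' @return a [landmark_set()].
#' @export
model_landmarks <- function(model, n_landmarks = 3) {
  stopifnot(inherits(model, "morphable_model"))
  if (is.null(model$landmarks))
    stop("model carries no landmark annotations")
  base <- c("nasion", "lpa", "rpa")
  ids <- model$landmarks[base]
  coords <- model$mean$vertices[ids, , drop = FALSE]
  if (n_landmarks == 3)
    return(landmark_set(base, coords, frame = "model"))
  if (n_landmarks != 7) stop("n_landmarks must be 3 or 7")
  if (is.null(model$frame)) stop("7-landmark sets need a model frame")
  ext <- pick_extremities(model$mean, model$frame)
  landmark_set(c(base, ext$names), rbind(coords, ext$coordinates),
               frame = "model")
}

#' Landmarks of a subject mesh in dense correspondence with a model
#'
#' Subject fiducials are read off the corresponded vertices (same indices
#' as on the mean mesh). Extremities are, by default, also taken at the
#' corresponded vertices of the template's extremities — the precise
#' choice enabled by dense correspondence; with `precise = FALSE` they are
#' instead picked by coordinate extremes in the subject's own frame, the
#' way an operator would approximate them.
#'
#' @param mesh the subject [trimesh()], corresponded with the model.
#' @param model the [morphable_model()].
#' @param frame the subject's [head_frame()] (needed for operator-style
#'   extremities).
#' @param n_landmarks 3 or 7.
#' @param precise use corresponded extremities (default) rather than
#'   frame-based extremes.
#' @return a [landmark_set()].
#' @export
subject_landmarks <- function(mesh, model, frame = NULL, n_landmarks = 3,
                              precise = TRUE) {
  if (is.null(model$landmarks)) stop("model carries no landmark annotations")
  base <- c("nasion", "lpa", "rpa")
  ids <- model$landmarks[base]
  coords <- mesh$vertices[ids, , drop = FALSE]
  if (n_landmarks == 3)
    return(landmark_set(base, coords, frame = "subject"))
  if (n_landmarks != 7) stop("n_landmarks must be 3 or 7")
  if (precise) {
    if (is.null(model$frame)) stop("corresponded extremities need a model frame")
    tmpl_ext <- pick_extremities(model$mean, model$frame)
    ext_ids <- attr(tmpl_ext, "vertex_ids")
    ext <- landmark_set(tmpl_ext$names, mesh$vertices[ext_ids, , drop = FALSE])
  } else {
    if (is.null(frame)) stop("operator-style extremities need the subject frame")
    ext <- pick_extremities(mesh, frame)
  }
  landmark_set(c(base, ext$names), rbind(coords, ext$coordinates),
               frame = "subject")
}
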