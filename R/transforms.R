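#' Head coordinate frame
#'
#' An origin plus three orthonormal axes declaring the anatomical
#' directions: `front` (towards the nasion), `left` and `up`. Used by the
#' sectioning of sampling walks and the extremity landmarks.
#'
#' @param origin 3-vector, head center.
#' @param front,left,up orthonormal unit 3-vectors.
#' @return object of class `head_frame`.
#' @export
head_frame <- function(origin = c(0, 0, 0), front = c(1, 0, 0),
                       left = c(0, 1, 0), up = c(0, 0, 1)) {
  A <- cbind(front, left, up)
  if (max(abs(crossprod(A) - diag(3))) > 1e-6)
    stop("frame axes must be orthonormal")
  structure(list(origin = as.numeric(origin), front = as.numeric(front),
                 left = as.numeric(left), up = as.numeric(up)),
            class = "head_frame")
}

#' Default head frame for an arbitrary mesh
#'
#' Falls back to PCA axes when no anatomical frame is declared: `up` is the
#' supplied superior direction snapped to the nearest principal axis, and
#' the remaining axes follow. Intended for interactive use; synthetic meshes
#' from this package carry an exact frame and never need the guess.
#'
#' @param mesh a [trimesh()].
#' @param superior approximate up direction (default +z).
#' @param anterior approximate front direction (default +x).
#' @return a [head_frame()].
#' @export
frame_from_pca <- function(mesh, superior = c(0, 0, 1), anterior = c(1, 0, 0)) {
  v <- as_points(mesh)
  ctr <- colMeans(v)
  ax <- eigen(stats::cov(v), symmetric = TRUE)$vectors
  pick <- function(dir, axes) {
    sc <- drop(crossprod(axes, dir))
    j <- which.max(abs(sc))
    list(axis = axes[, j] * sign(sc[j]), rest = axes[, -j, drop = FALSE])
  }
  u <- pick(superior, ax)
  f <- pick(anterior, u$rest)
  front <- f$axis - u$axis * sum(f$axis * u$axis)
  front <- front / sqrt(sum(front^2))
  left <- cross3(u$axis, front)
  head_frame(origin = ctr, front = front, left = left, up = u$axis)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Pose parameters of a non-uniform similarity transform
#'
#' A transform `x -> R %*% (scale * x) + translation`, with the rotation
#' parameterized as an axis-angle 3-vector. The scale is per-axis
#' (non-uniform) and strictly positive.
#'
#' @param scale positive length-3 vector (or scalar, recycled).
#' @param rotation axis-angle 3-vector (radians).
#' @param translation 3-vector, vertex units.
#' @return object of class `head_pose`.
#' @export
head_pose <- function(scale = c(1, 1, 1), rotation = c(0, 0, 0),
                      translation = c(0, 0, 0)) {
  scale <- rep_len(as.numeric(scale), 3L)
  if (any(scale <= 0)) stop("scale components must be positive")
  structure(list(scale = scale, rotation = as.numeric(rotation),
                 translation = as.numeric(translation)),
            class = "head_pose")
}

#' @export
print.head_pose <- function(x, ...) {
  ang <- sqrt(sum(x$rotation^2))
  cat(sprintf("head_pose: scale (%s), rotation %.3f deg, translation (%s)\n",
              paste(signif(x$scale, 4), collapse = ", "), ang * 180 / pi,
              paste(signif(x$translation, 4), collapse = ", ")))
  invisible(x)
}

#' Rotation matrix from an axis-angle vector (Rodrigues)
#'
#' @param w axis-angle 3-vector; its norm is the angle in radians.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_matrix <- function(w) {
  th <- sqrt(sum(w^2))
  K <- skew3(w)
  if (th < 1e-12) return(diag(3) + K + 0.5 * K %*% K)
  diag(3) + sin(th) / th * K + (1 - cos(th)) / th^2 * K %*% K
}

skew3 <- function(w) {
  matrix(c(0, w[3], -w[2],
           -w[3], 0, w[1],
           w[2], -w[1], 0), 3, 3)
}

#' Axis-angle vector from a rotation matrix
#'
#' @param R 3 x 3 rotation matrix.
#' @return axis-angle 3-vector.
#' @export
axis_angle <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  th <- acos(ct)
  if (th < 1e-12) return(c(0, 0, 0))
  if (abs(pi - th) < 1e-6) {
    # near 180 degrees: axis from the symmetric part
    B <- (R + diag(3)) / 2
    axis <- sqrt(pmax(diag(B), 0))
    j <- which.max(axis)
    if (j == 1) { axis[2] <- B[1, 2] / axis[1]; axis[3] <- B[1, 3] / axis[1] }
    if (j == 2) { axis[1] <- B[1, 2] / axis[2]; axis[3] <- B[2, 3] / axis[2] }
    if (j == 3) { axis[1] <- B[1, 3] / axis[3]; axis[2] <- B[2, 3] / axis[3] }
    return(axis / sqrt(sum(axis^2)) * th)
  }
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  v / (2 * sin(th)) * th
}

# Partial derivatives dR/dw_i of the Rodrigues map (Gallego & Yezzi form).
rotation_matrix_grad <- function(w) {
  th2 <- sum(w^2)
  R <- rotation_matrix(w)
  out <- vector("list", 3L)
  if (th2 < 1e-16) {
    for (i in 1:3) {
      e <- numeric(3); e[i] <- 1
      out[[i]] <- skew3(e)
    }
    return(out)
  }
  ImR <- diag(3) - R
  for (i in 1:3) {
    e <- numeric(3); e[i] <- 1
    out[[i]] <- (w[i] * skew3(w) + skew3(cross3(w, drop(ImR %*% e)))) %*% R / th2
  }
  out
}

#' Homogeneous 4 x 4 matrix of a pose
#'
#' Composition order is Translate o Rotate o Scale: the linear block is
#' `R %*% diag(scale)` and the last column holds the translation.
#'
#' @param pose a [head_pose()].
#' @return 4 x 4 matrix.
#' @export
pose_matrix <- function(pose) {
  T <- diag(4)
  T[1:3, 1:3] <- rotation_matrix(pose$rotation) %*% diag(pose$scale)
  T[1:3, 4] <- pose$translation
  T
}

#' Apply a pose to points
#'
#' @param pose a [head_pose()].
#' @param points q x 3 coordinates (or [trimesh()] / [point_cloud()], in
#'   which case an object of the same kind is returned).
#' @return transformed coordinates (same container as the input).
#' @export
apply_pose <- function(pose, points) {
  if (inherits(points, "trimesh")) {
    out <- points
    out$vertices <- apply_pose(pose, points$vertices)
    if (!is.null(points$normals)) {
      # normals transform by the inverse-transpose of the linear block
      N <- sweep(points$normals, 2, pose$scale, "/") %*%
        t(rotation_matrix(pose$rotation))
      out$normals <- N / sqrt(rowSums(N^2))
    }
    return(out)
  }
  p <- as_points(points)
  R <- rotation_matrix(pose$rotation)
  sweep(p, 2, pose$scale, "*") %*% t(R) +
    matrix(pose$translation, nrow(p), 3, byrow = TRUE)
}

# Transform a head frame by a pose; axes are re-orthonormalized because a
# non-uniform scale does not preserve angles exactly.
transform_frame <- function(frame, pose) {
  R <- rotation_matrix(pose$rotation)
  lin <- function(a) drop(R %*% (pose$scale * a))
  f <- lin(frame$front); f <- f / sqrt(sum(f^2))
  u0 <- lin(frame$up)
  u <- u0 - f * sum(u0 * f); u <- u / sqrt(sum(u^2))
  l <- cross3(u, f)
  head_frame(origin = drop(apply_pose(pose, matrix(frame$origin, 1))),
             front = f, left = l, up = u)
}

# Frobenius norm of the difference of two pose matrices.
pose_matrix_dist <- function(pose, pose0) {
  sqrt(sum((pose_matrix(pose) - pose_matrix(pose0))^2))
}
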