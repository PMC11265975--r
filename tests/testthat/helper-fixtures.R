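# Small geometric fixtures built in code.

# Unit cube: 8 vertices, 12 triangles, consistently wound.
cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = c(0, 1), y = c(0, 1), z = c(0, 1)))
  dimnames(v) <- NULL
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  trimesh(v, f)
}

# A 3-4-5 right triangle as a one-face mesh.
right_triangle_mesh <- function() {
  trimesh(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)),
          rbind(c(1, 2, 3)))
}

# Random jittered sphere-ish mesh, seeded (valid topology, irregular
# geometry).
random_mesh <- function(seed = 1, resolution = 2, jitter = 0.1) {
  m <- subdivided_sphere(resolution)
  m$vertices <- m$vertices +
    scalpfit:::with_seed(seed, matrix(rnorm(length(m$vertices), sd = jitter),
                                      nrow(m$vertices)))
  trimesh(m$vertices, m$faces)
}

random_points <- function(n, seed = 1, scale = 10) {
  scalpfit:::with_seed(seed, matrix(runif(3 * n, -scale, scale), n))
}

# O(nm) nearest-neighbor oracle written independently in R.
nn_oracle <- function(query, target) {
  idx <- integer(nrow(query))
  dist <- numeric(nrow(query))
  for (i in seq_len(nrow(query))) {
    d <- sqrt(colSums((t(target) - query[i, ])^2))
    idx[i] <- which.min(d)
    dist[i] <- d[idx[i]]
  }
  list(index = idx, distance = dist)
}

rotation_angle_deg <- function(R1, R2) {
  acos(pmin(1, pmax(-1, (sum(diag(crossprod(R1, R2))) - 1) / 2))) * 180 / pi
}

# Small toy morphable model on a jittered sphere template (k smooth modes).
toy_model <- function(k = 3, resolution = 2, amplitudes = c(40, 25, 15)) {
  tpl <- make_template_head(resolution)
  true_model(tpl, k, amplitudes[seq_len(k)])
}
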