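# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. With seed = NULL the code runs on the
# ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

#' Angular sectioning of the scalp for sampling walks
#'
#' Divides the head into `n_steps + 1` sections of equal angular extent
#' around the left-right axis through the head center, ordered along the
#' arc from the frontmost point over the top towards the back and neck.
#' Each section is further split into three equal-angle sub-sections by the
#' latitude from the midline plane: 1 = low (near the ear), 2 = middle,
#' 3 = high (near the midline/crown). The sub-sections anchor the vertical
#' zigzag of the non-random sampling strategies.
#'
#' @param mesh a [trimesh()].
#' @param graph its [build_edge_graph()] (used to require connectivity).
#' @param n_steps number of walk steps (>= 1); gives `n_steps + 1` sections.
#' @param frame a [head_frame()] declaring front/left/up.
#' @return object of class `section_map` with per-vertex `section`
#'   (1..n_sections), `subsection` (1..3), `hemisphere` (+1 left, -1 right,
#'   0 midline), the arc angle `theta`, the latitude `lat`, and the frame.
#' @export
partition_sections <- function(mesh, graph, n_steps, frame) {
  stopifnot(inherits(mesh, "trimesh"), inherits(frame, "head_frame"))
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (!is_connected_mesh(mesh))
    stop("mesh is not a single connected component")
  v <- sweep(mesh$vertices, 2, frame$origin)
  f <- drop(v %*% frame$front)
  u <- drop(v %*% frame$up)
  l <- drop(v %*% frame$left)
  theta <- atan2(u, f)
  theta <- ifelse(theta < 0, theta + 2 * pi, theta)
  n_sections <- n_steps + 1L
  rng <- range(theta)
  width <- (rng[2] - rng[1]) / n_sections
  section <- pmin(floor((theta - rng[1]) / width) + 1L, n_sections)
  if (length(unique(section)) < n_sections) {
    empty <- setdiff(seq_len(n_sections), unique(section))
    stop("empty section(s) ", paste(empty, collapse = ", "),
         ": mesh too coarse for n_steps = ", n_steps)
  }
  r <- sqrt(rowSums(v^2))
  lat <- asin(pmin(1, abs(l) / pmax(r, 1e-12)))
  subsection <- pmin(3L, floor(3 * (1 - lat / (pi / 2))) + 1L)
  hemisphere <- sign(l)
  structure(list(section = as.integer(section),
                 subsection = as.integer(subsection),
                 hemisphere = hemisphere, theta = theta, lat = lat,
                 n_sections = n_sections, frame = frame,
                 lateral = l),
            class = "section_map")
}

#' @export
print.section_map <- function(x, ...) {
  cat(sprintf("section_map: %d sections x 3 sub-sections over %d vertices\n",
              x$n_sections, length(x$section)))
  invisible(x)
}

new_trajectory <- function(points, vertex_ids = NULL, normals = NULL,
                           step_index = NULL, geodesic_length = NA_real_,
                           strategy = NA_character_, seed = NA_integer_) {
  points <- as_points(points)
  structure(list(points = points, vertex_ids = vertex_ids, normals = normals,
                 step_index = step_index,
                 length = polyline_length(points),
                 geodesic_length = geodesic_length,
                 strategy = strategy, seed = seed),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory (%s): %d points, length %.1f mm, geodesic %.1f mm\n",
              x$strategy, nrow(x$points), x$length, x$geodesic_length))
  invisible(x)
}

#' Simulate a sparse contiguous sampling walk over the scalp
#'
#' Emulates the movement of a tracked pointer over the head as a constrained
#' walk on the mesh-edge graph. The non-random strategies move in a zigzag
#' between adjacent angular sections: each step is a weighted-shortest
#' (Dijkstra) path from a seeded-random start vertex in section i to a
#' seeded-random end vertex in section i + 1, restricted to the vertices of
#' those two sections; step endpoints alternate between the low and high
#' sub-sections to force the vertical oscillation. The first step starts at
#' the pre-auricular area (the lateral extreme of the first section's low
#' sub-section). Steps are semi-continuous: contiguous along graph edges
#' within a step, with short seeded jumps between steps.
#'
#' * `side_to_top`: two passes (left hemisphere then right).
#' * `half_side_to_top`: a single pass on the left hemisphere.
#' * `side_to_side`: a single pass whose endpoints alternate hemisphere,
#'   crossing the midline on every step.
#' * `random_walk`: uniform random moves to adjacent vertices until the
#'   accumulated Euclidean length reaches `target_length`; revisits allowed.
#'
#' @param mesh a [trimesh()].
#' @param graph its [build_edge_graph()].
#' @param sections a [partition_sections()] result with `n_steps + 1`
#'   sections (ignored by `random_walk` except for the frame).
#' @param strategy one of `"side_to_top"`, `"side_to_side"`,
#'   `"half_side_to_top"`, `"random_walk"`.
#' @param n_steps number of steps per pass.
#' @param seed integer seed; the walk is a pure function of
#'   (mesh, n_steps, seed).
#' @param target_length Euclidean stopping length for `random_walk`
#'   (default `105 * n_steps` mm, matching 1-16 steps spanning
#'   roughly 0.3-1.7 m on an adult head).
#' @param k_normals neighborhood size for sample-normal estimation.
#' @return a `trajectory`: ordered `points`, source `vertex_ids`, estimated
#'   outward `normals`, per-point `step_index`, accumulated Euclidean
#'   `length`, `geodesic_length` (sum of traversed edge weights), strategy
#'   and seed.
#' @export
sample_strategy <- function(mesh, graph, sections,
                            strategy = c("side_to_top", "side_to_side",
                                         "half_side_to_top", "random_walk"),
                            n_steps, seed, target_length = NULL,
                            k_normals = 10L) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(mesh, "trimesh"), inherits(graph, "edge_graph"),
            inherits(sections, "section_map"))
  if (strategy != "random_walk" && sections$n_sections != n_steps + 1L)
    stop("sections were built for a different n_steps")
  ids <- with_seed(seed, switch(
    strategy,
    side_to_top = c(walk_pass(mesh, graph, sections, n_steps, hemi = +1),
                    walk_pass(mesh, graph, sections, n_steps, hemi = -1)),
    half_side_to_top = walk_pass(mesh, graph, sections, n_steps, hemi = +1),
    side_to_side = walk_pass(mesh, graph, sections, n_steps, hemi = NULL,
                             alternate_hemi = TRUE),
    random_walk = list(random_walk_ids(
      mesh, graph, sections,
      if (is.null(target_length)) 105 * n_steps else target_length))
  ))
  steps <- rep(seq_along(ids), lengths(ids))
  vid <- unlist(ids, use.names = FALSE)
  # drop consecutive duplicates at step junctions
  dup <- c(FALSE, vid[-1] == vid[-length(vid)])
  vid <- vid[!dup]
  steps <- steps[!dup]
  pts <- mesh$vertices[vid, , drop = FALSE]
  geo <- 0
  if (length(vid) > 1) {
    seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                           pts[-nrow(pts), , drop = FALSE])^2))
    geo <- sum(seg[steps[-1] == steps[-length(steps)]])
  }
  ctr <- sections$frame$origin
  normals <- if (nrow(pts) > k_normals) {
    estimate_sample_normals(pts, k_normals, ctr)$normals
  } else {
    d <- sweep(pts, 2, ctr)
    d / sqrt(rowSums(d^2))
  }
  new_trajectory(points = pts, vertex_ids = vid, normals = normals,
                 step_index = steps, geodesic_length = geo,
                 strategy = strategy, seed = seed)
}

# One zigzag pass. hemi: +1 left, -1 right, NULL for both; alternate_hemi
# alternates the endpoint hemisphere per section boundary (side-to-side).
walk_pass <- function(mesh, graph, sections, n_steps, hemi,
                      alternate_hemi = FALSE) {
  ig <- as_igraph(graph)
  hemi_mask <- function(h) {
    if (is.null(h)) rep(TRUE, length(sections$hemisphere))
    else if (h > 0) sections$hemisphere >= 0 else sections$hemisphere <= 0
  }
  region <- function(sec, h, sub) {
    idx <- which(sections$section == sec & hemi_mask(h))
    if (!is.null(sub)) {
      narrowed <- idx[sections$subsection[idx] == sub]
      if (length(narrowed) > 0) idx <- narrowed
    }
    idx
  }
  boundary_hemi <- function(j) {
    if (!alternate_hemi) hemi else if (j %% 2L == 1L) +1 else -1
  }
  # anchor sub-sections alternate low (1) / high (3) along the arc
  anchor <- function(j) if (j %% 2L == 1L) 1L else 3L
  preauricular <- function(h) {
    idx <- region(1L, h, 1L)
    idx[which.max(abs(sections$lateral[idx]))]
  }
  out <- vector("list", n_steps)
  for (i in seq_len(n_steps)) {
    h_start <- boundary_hemi(i)
    h_end <- boundary_hemi(i + 1L)
    start_region <- region(i, h_start, anchor(i))
    end_region <- region(i + 1L, h_end, anchor(i + 1L))
    if (length(start_region) == 0L || length(end_region) == 0L)
      stop("step ", i, ": empty start or end region")
    start <- if (i == 1L) preauricular(h_start)
             else start_region[sample.int(length(start_region), 1L)]
    end <- end_region[sample.int(length(end_region), 1L)]
    allowed <- which(sections$section %in% c(i, i + 1L) &
                       (hemi_mask(h_start) | hemi_mask(h_end)))
    allowed <- union(allowed, c(start, end))
    sub <- igraph::induced_subgraph(ig, as.character(allowed))
    path <- suppressWarnings(igraph::shortest_paths(
      sub, from = as.character(start), to = as.character(end),
      weights = igraph::E(sub)$weight, output = "vpath")$vpath[[1]])
    if (length(path) == 0L && start != end)
      stop("step ", i, ": restricted section region is disconnected")
    out[[i]] <- if (length(path) == 0L) start
                else as.integer(igraph::V(sub)$name[path])
  }
  out
}

# Uniform random adjacent-vertex moves until the accumulated Euclidean
# length reaches `target_length`.
random_walk_ids <- function(mesh, graph, sections, target_length) {
  n <- nrow(mesh$vertices)
  adj <- vector("list", n)
  e <- graph$edges
  both <- rbind(e, e[, 2:1])
  ord <- order(both[, 1], both[, 2])
  both <- both[ord, , drop = FALSE]
  adj <- split(both[, 2], factor(both[, 1], levels = seq_len(n)))
  idx <- which(sections$section == 1L & sections$subsection == 1L &
                 sections$hemisphere >= 0)
  if (length(idx) == 0L) idx <- which(sections$section == 1L)
  cur <- idx[which.max(abs(sections$lateral[idx]))]
  ids <- cur
  total <- 0
  max_moves <- 200000L
  while (total < target_length && length(ids) < max_moves) {
    nbrs <- adj[[cur]]
    nxt <- nbrs[sample.int(length(nbrs), 1L)]
    total <- total + sqrt(sum((mesh$vertices[nxt, ] - mesh$vertices[cur, ])^2))
    ids <- c(ids, nxt)
    cur <- nxt
  }
  ids
}

#' Estimate outward sample normals from the samples alone
#'
#' The normal at each sample is the smallest-variance direction of the
#' covariance of its k nearest neighboring samples, with the sign flipped so
#' it points away from the head center. Neighborhoods whose two smallest
#' covariance eigenvalues are both (near) zero are collinear and carry no
#' normal information; those fall back to the radial direction and are
#' flagged.
#'
#' @param points q x 3 sample coordinates (q > k_neighbors).
#' @param k_neighbors neighborhood size (>= 3).
#' @param head_center 3-vector used to orient normals outward.
#' @return a [point_cloud()] with normals; attribute `fallback` flags the
#'   points where the radial fallback was used.
#' @export
estimate_sample_normals <- function(points, k_neighbors, head_center) {
  p <- as_points(points)
  q <- nrow(p)
  if (k_neighbors < 3) stop("k_neighbors must be >= 3")
  if (q <= k_neighbors) stop("need more points than k_neighbors")
  d2 <- as.matrix(stats::dist(p))
  normals <- matrix(0, q, 3)
  fallback <- logical(q)
  for (i in seq_len(q)) {
    nb <- order(d2[i, ])[seq_len(k_neighbors + 1L)]  # includes the point
    C <- stats::cov(p[nb, , drop = FALSE])
    eg <- eigen(C, symmetric = TRUE)
    if (eg$values[2] < 1e-12 * max(eg$values[1], 1e-300)) {
      dir <- p[i, ] - head_center
      normals[i, ] <- dir / sqrt(sum(dir^2))
      fallback[i] <- TRUE
    } else {
      normals[i, ] <- eg$vectors[, 3]
    }
  }
  flip <- rowSums(normals * sweep(p, 2, head_center)) < 0
  normals[flip, ] <- -normals[flip, , drop = FALSE]
  out <- point_cloud(p, normals = normals)
  attr(out, "fallback") <- fallback
  out
}

#' Fraction of the surface reached by a trajectory
#'
#' The fraction of mesh vertices lying within `radius` of any trajectory
#' point.
#'
#' @param trajectory a `trajectory` (or bare q x 3 point matrix).
#' @param mesh a [trimesh()].
#' @param radius coverage radius (> 0), vertex units.
#' @return fraction in [0, 1].
#' @export
surface_coverage <- function(trajectory, mesh, radius) {
  if (radius <= 0) stop("radius must be positive")
  pts <- if (inherits(trajectory, "trajectory")) trajectory$points
         else as_points(trajectory)
  d <- nearest_neighbors(mesh$vertices, pts)$distance
  mean(d <= radius)
}
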