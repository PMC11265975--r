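#' Triangle mesh
#'
#' Constructs a triangle mesh from a vertex matrix and a face index matrix.
#' Edges are derived from the faces (the deduplicated union of face sides).
#' Coordinates are assumed to be in millimeters unless stated otherwise.
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates.
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @param normals optional n x 3 matrix of unit vertex normals.
#' @param validate check invariants (index ranges, normal unit length).
#' @return an object of class `trimesh` with components `vertices`, `faces`,
#'   `edges` (l x 2, each row sorted, unique) and optionally `normals`.
#' @export
trimesh <- function(vertices, faces, normals = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (validate) {
    if (anyNA(vertices)) stop("vertices contain NA")
    if (any(faces < 1L) || any(faces > nrow(vertices)))
      stop("face indices out of range [1, n]")
  }
  edges <- edges_from_faces(faces)
  m <- list(vertices = vertices, faces = faces, edges = edges)
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    if (validate) {
      if (!all(dim(normals) == dim(vertices)))
        stop("normals must match vertices in shape")
      len <- sqrt(rowSums(normals^2))
      if (any(abs(len - 1) > 1e-9)) stop("vertex normals must have unit length")
    }
    m$normals <- normals
  }
  structure(m, class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("trimesh: %d vertices, %d faces, %d edges%s\n",
              nrow(x$vertices), nrow(x$faces), nrow(x$edges),
              if (is.null(x$normals)) "" else ", with vertex normals"))
  invisible(x)
}

# Deduplicated union of face sides, each row sorted ascending.
edges_from_faces <- function(faces) {
  e <- rbind(faces[, c(1, 2), drop = FALSE],
             faces[, c(2, 3), drop = FALSE],
             faces[, c(3, 1), drop = FALSE])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  storage.mode(e) <- "integer"
  e
}

#' Point cloud
#'
#' A light container for an (ordered or unordered) set of 3D points with
#' optional unit normals.
#'
#' @param points numeric q x 3 matrix.
#' @param normals optional q x 3 matrix of unit vectors.
#' @return an object of class `point_cloud`.
#' @export
point_cloud <- function(points, normals = NULL) {
  points <- as_points(points)
  if (nrow(points) < 1L) stop("point cloud must contain at least one point")
  pc <- list(points = points)
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    if (!all(dim(normals) == dim(points))) stop("normals shape mismatch")
    len <- sqrt(rowSums(normals^2))
    if (any(abs(len - 1) > 1e-6)) stop("point normals must have unit length")
    pc$normals <- normals
  }
  structure(pc, class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points%s\n", nrow(x$points),
              if (is.null(x$normals)) "" else ", with normals"))
  invisible(x)
}

# Coerce trimesh / point_cloud / matrix to a plain coordinate matrix.
as_points <- function(x) {
  if (inherits(x, "trimesh")) return(x$vertices)
  if (inherits(x, "point_cloud")) return(x$points)
  x <- as.matrix(x)
  if (is.null(dim(x)) || ncol(x) != 3L) stop("expected q x 3 coordinates")
  storage.mode(x) <- "double"
  x
}

#' Per-vertex normals by area-weighted face-normal accumulation
#'
#' Each vertex normal is the normalized sum of the (unnormalized) cross
#' products of its incident faces; the cross-product magnitude equals twice
#' the face area, which yields the area weighting. Orientation is fixed
#' globally per connected component by majority vote of the sign of
#' `dot(normal, vertex - component centroid)`, so that closed convex-ish
#' meshes come out with outward normals regardless of face winding.
#'
#' @param mesh a [trimesh()].
#' @return the mesh with a `normals` component of unit vectors.
#' @export
compute_vertex_normals <- function(mesh) {
  stopifnot(inherits(mesh, "trimesh"))
  if (nrow(mesh$faces) < 1L) stop("mesh has no faces")
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  area2 <- sqrt(rowSums(fn^2))
  keep <- area2 > 1e-300
  if (!any(keep)) stop("all faces are degenerate (zero area)")
  fn <- fn[keep, , drop = FALSE]
  fk <- f[keep, , drop = FALSE]
  n <- matrix(0, nrow(v), 3)
  for (j in 1:3) {
    n[, 1] <- n[, 1] + unname(tapply2(fn[, 1], fk[, j], nrow(v)))
    n[, 2] <- n[, 2] + unname(tapply2(fn[, 2], fk[, j], nrow(v)))
    n[, 3] <- n[, 3] + unname(tapply2(fn[, 3], fk[, j], nrow(v)))
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  comp <- vertex_components(nrow(v), mesh$edges)
  for (cid in unique(comp)) {
    sel <- comp == cid
    ctr <- colMeans(v[sel, , drop = FALSE])
    outward <- rowSums(n[sel, , drop = FALSE] *
                         sweep(v[sel, , drop = FALSE], 2, ctr))
    if (sum(outward < 0) > sum(outward > 0)) n[sel, ] <- -n[sel, ]
  }
  mesh$normals <- n
  mesh
}

# Sum `x` grouped by integer index `g` into a length-n vector.
tapply2 <- function(x, g, n) {
  out <- numeric(n)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# Connected-component label per vertex from an edge list.
vertex_components <- function(n, edges) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::components(g)$membership
}

#' Is the mesh a single connected component?
#'
#' Sampling walks require a connected edge graph; this check is explicit
#' rather than silently assumed.
#'
#' @param mesh a [trimesh()].
#' @return logical.
#' @export
is_connected_mesh <- function(mesh) {
  length(unique(vertex_components(nrow(mesh$vertices), mesh$edges))) == 1L
}

#' Weighted mesh-edge graph
#'
#' One node per mesh vertex, one undirected edge per unique mesh edge, the
#' weight being the Euclidean distance along the edge.
#'
#' @param mesh a [trimesh()].
#' @return object of class `edge_graph` with `nodes`, `edges`, `weights`.
#' @export
build_edge_graph <- function(mesh) {
  stopifnot(inherits(mesh, "trimesh"))
  e <- mesh$edges
  d <- mesh$vertices[e[, 1], , drop = FALSE] - mesh$vertices[e[, 2], , drop = FALSE]
  w <- sqrt(rowSums(d^2))
  structure(list(nodes = seq_len(nrow(mesh$vertices)), edges = e, weights = w),
            class = "edge_graph")
}

#' @export
print.edge_graph <- function(x, ...) {
  cat(sprintf("edge_graph: %d nodes, %d weighted edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# igraph view of an edge_graph, vertices named by index for stable mapping
# through induced subgraphs.
as_igraph <- function(graph) {
  g <- igraph::graph_from_edgelist(graph$edges, directed = FALSE)
  if (igraph::vcount(g) < length(graph$nodes))
    g <- igraph::add_vertices(g, length(graph$nodes) - igraph::vcount(g))
  igraph::E(g)$weight <- graph$weights
  igraph::V(g)$name <- as.character(graph$nodes)
  g
}

#' Nearest neighbors between point clouds
#'
#' For each query point, the index of the closest target point and the
#' Euclidean distance, computed by exhaustive scan. Ties are broken by the
#' lowest target index.
#'
#' @param query,target point clouds (matrix, [point_cloud()] or [trimesh()]).
#' @return list with `index` (into the target) and `distance`.
#' @export
nearest_neighbors <- function(query, target) {
  q <- as_points(query)
  t <- as_points(target)
  if (nrow(q) < 1L) stop("empty query point set")
  if (nrow(t) < 1L) stop("empty target point set")
  .nn_brute(q, t)
}

#' Accumulated length of an ordered polyline
#'
#' Sum of Euclidean distances between consecutive points; 0 for a single
#' point.
#'
#' @param points ordered q x 3 coordinates.
#' @return total length (same units as the coordinates).
#' @export
polyline_length <- function(points) {
  p <- as_points(points)
  if (nrow(p) < 2L) return(0)
  d <- diff(p)
  sum(sqrt(rowSums(d^2)))
}

#' Crop a mesh to the vertices closer to a reference region
#'
#' Keeps vertices whose nearest-neighbor distance to `reference_region` is
#' smaller (by at least `margin`) than to `other_region`; faces touching a
#' removed vertex are dropped. Used to isolate the scalp from the rest of an
#' aligned head template. Distances are vertex-to-vertex by default; set
#' `to_surface = TRUE` to measure against the regions' triangle midpoints as
#' a denser stand-in for point-to-surface distance when the regions are
#' meshes.
#'
#' @param mesh a [trimesh()], already aligned to the reference shape.
#' @param reference_region,other_region point sets.
#' @param margin required distance advantage of the reference (default 0).
#' @param to_surface densify mesh regions with face midpoints before
#'   measuring.
#' @return the cropped [trimesh()]; attribute `kept` holds the original
#'   vertex indices.
#' @export
crop_by_reference_proximity <- function(mesh, reference_region, other_region,
                                        margin = 0, to_surface = FALSE) {
  stopifnot(inherits(mesh, "trimesh"))
  densify <- function(x) {
    if (to_surface && inherits(x, "trimesh")) {
      mid <- (x$vertices[x$faces[, 1], ] + x$vertices[x$faces[, 2], ] +
                x$vertices[x$faces[, 3], ]) / 3
      rbind(x$vertices, mid)
    } else as_points(x)
  }
  d_ref <- nearest_neighbors(mesh$vertices, densify(reference_region))$distance
  d_oth <- nearest_neighbors(mesh$vertices, densify(other_region))$distance
  keep <- which(d_ref + margin < d_oth)
  if (length(keep) == 0L) stop("proximity crop removed every vertex")
  submesh(mesh, keep)
}

# Sub-mesh on a vertex subset; faces with any removed vertex are dropped.
submesh <- function(mesh, keep) {
  keep <- sort(unique(as.integer(keep)))
  map <- integer(nrow(mesh$vertices))
  map[keep] <- seq_along(keep)
  fkeep <- rowSums(matrix(mesh$faces %in% keep, ncol = 3)) == 3L
  faces <- matrix(map[mesh$faces[fkeep, , drop = FALSE]], ncol = 3)
  out <- trimesh(mesh$vertices[keep, , drop = FALSE], faces,
                 normals = if (!is.null(mesh$normals))
                   mesh$normals[keep, , drop = FALSE],
                 validate = FALSE)
  attr(out, "kept") <- keep
  out
}
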