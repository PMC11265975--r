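test_that("vertex normals point outward on a convex solid and match a face-accumulation oracle", {
  cube <- compute_vertex_normals(cube_mesh())
  ctr <- colMeans(cube$vertices)
  expect_true(all(rowSums(cube$normals * sweep(cube$vertices, 2, ctr)) > 0))
  expect_equal(sqrt(rowSums(cube$normals^2)), rep(1, 8), tolerance = 1e-12)

  m <- random_mesh(seed = 3)
  m <- compute_vertex_normals(m)
  # independent oracle: explicit loop over faces, unnormalized cross products
  acc <- matrix(0, nrow(m$vertices), 3)
  for (i in seq_len(nrow(m$faces))) {
    f <- m$faces[i, ]
    nrm <- scalpfit:::cross3(m$vertices[f[2], ] - m$vertices[f[1], ],
                             m$vertices[f[3], ] - m$vertices[f[1], ])
    for (v in f) acc[v, ] <- acc[v, ] + nrm
  }
  acc <- acc / sqrt(rowSums(acc^2))
  ctr <- colMeans(m$vertices)
  if (sum(rowSums(acc * sweep(m$vertices, 2, ctr)) < 0) > nrow(acc) / 2)
    acc <- -acc
  expect_equal(m$normals, acc, tolerance = 1e-12)
})

test_that("sphere vertex normals are radial at the tessellation's O(h) accuracy", {
  dev <- vapply(3:4, function(r) {
    s <- compute_vertex_normals(subdivided_sphere(r, 10))
    max(acos(pmin(1, abs(rowSums(s$normals * s$vertices / 10)))))
  }, 0)
  expect_lt(dev[1], 0.06)
  expect_lt(dev[2], 0.03)
  # deviation shrinks with the edge length
  expect_lt(dev[2], 0.6 * dev[1])
})

test_that("degenerate faces are skipped and all-degenerate meshes error", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 1, 0))
  m <- trimesh(v, rbind(c(1, 2, 3), c(1, 2, 4)))  # first face has zero area
  m <- compute_vertex_normals(m)
  expect_equal(abs(m$normals[c(1, 2, 4), 3]), rep(1, 3), tolerance = 1e-12)
  # vertex 3 only touches the degenerate face: no normal information
  expect_equal(m$normals[3, ], c(0, 0, 0))
  flat <- trimesh(v[1:3, ], rbind(c(1, 2, 3)))
  expect_error(compute_vertex_normals(flat), "degenerate")
})

test_that("edge graph carries one weighted edge per unique face side", {
  tri <- right_triangle_mesh()
  g <- build_edge_graph(tri)
  expect_equal(nrow(g$edges), 3L)
  expect_setequal(round(g$weights, 10), c(3, 4, 5))

  two <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
                 rbind(c(1, 2, 3), c(2, 4, 3)))
  expect_equal(nrow(build_edge_graph(two)$edges), 5L)

  m <- random_mesh(seed = 9)
  g <- build_edge_graph(m)
  # set-based dedup oracle
  sides <- rbind(m$faces[, 1:2], m$faces[, 2:3], m$faces[, c(3, 1)])
  key <- unique(paste(pmin(sides[, 1], sides[, 2]),
                      pmax(sides[, 1], sides[, 2])))
  expect_equal(nrow(g$edges), length(key))
  expect_true(all(g$weights > 0))
  d <- sqrt(rowSums((m$vertices[g$edges[, 1], ] -
                       m$vertices[g$edges[, 2], ])^2))
  expect_equal(g$weights, d, tolerance = 1e-12)
})

test_that("nearest neighbors match the brute-force oracle exactly", {
  q <- random_points(200, seed = 2)
  t <- random_points(150, seed = 4)
  nn <- nearest_neighbors(q, t)
  or <- nn_oracle(q, t)
  expect_identical(nn$index, or$index)
  expect_equal(nn$distance, or$distance, tolerance = 1e-12)

  nn_self <- nearest_neighbors(q, q)
  expect_identical(nn_self$index, seq_len(nrow(q)))
  expect_equal(nn_self$distance, rep(0, nrow(q)))

  nn1 <- nearest_neighbors(rbind(c(0, 0, 0)), rbind(c(3, 4, 0), c(10, 0, 0)))
  expect_identical(nn1$index, 1L)
  expect_equal(nn1$distance, 5)

  # tie broken by lowest target index
  tie <- nearest_neighbors(rbind(c(0, 0, 0)),
                           rbind(c(1, 0, 0), c(-1, 0, 0), c(1, 0, 0)))
  expect_identical(tie$index, 1L)
  expect_error(nearest_neighbors(q, q[0, , drop = FALSE]), "empty")
})

test_that("polyline length accumulates consecutive distances and is additive", {
  expect_equal(polyline_length(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))), 2)
  expect_equal(polyline_length(rbind(c(5, 5, 5))), 0)
  p <- random_points(100, seed = 6)
  oracle <- sum(vapply(2:100, function(i)
    sqrt(sum((p[i, ] - p[i - 1, ])^2)), 0))
  expect_equal(polyline_length(p), oracle, tolerance = 1e-12)
  a <- p[1:40, ]
  b <- p[41:100, ]
  expect_equal(polyline_length(p),
               polyline_length(a) + polyline_length(b) +
                 sqrt(sum((a[40, ] - b[1, ])^2)),
               tolerance = 1e-12)
})

test_that("proximity crop keeps the vertices closer to the reference region", {
  m <- subdivided_sphere(2, 10)
  # reference is the whole mesh, competitor far away: identity crop
  far <- matrix(c(1000, 0, 0), 1)
  full <- crop_by_reference_proximity(m, m$vertices, far)
  expect_equal(nrow(full$vertices), nrow(m$vertices))
  expect_equal(full$vertices, m$vertices)

  # hemisphere split against the per-vertex two-distance oracle
  up <- m$vertices[m$vertices[, 3] > 0.3 * 10, , drop = FALSE]
  dn <- m$vertices[m$vertices[, 3] < -0.3 * 10, , drop = FALSE]
  cropped <- crop_by_reference_proximity(m, up, dn)
  d_up <- nn_oracle(m$vertices, up)$distance
  d_dn <- nn_oracle(m$vertices, dn)$distance
  expect_identical(sort(attr(cropped, "kept")), which(d_up < d_dn))

  expect_error(crop_by_reference_proximity(m, up, dn, margin = 1000),
               "every vertex")
})

test_that("mesh construction validates indices and normals", {
  expect_error(trimesh(matrix(0, 3, 3), rbind(c(1, 2, 4))), "out of range")
  expect_error(trimesh(matrix(rnorm(9), 3), rbind(c(1, 2, 3)),
                       normals = matrix(2, 3, 3)), "unit length")
  expect_true(is_connected_mesh(cube_mesh()))
  two_comp <- trimesh(rbind(matrix(rnorm(9), 3), matrix(rnorm(9), 3) + 10),
                      rbind(c(1, 2, 3), c(4, 5, 6)))
  expect_false(is_connected_mesh(two_comp))
})

test_that("exact point-to-surface distance agrees with geometry", {
  tri <- right_triangle_mesh()
  # above the interior: perpendicular distance
  ps <- point_to_surface_distance(rbind(c(0.5, 0.5, 2)), tri)
  expect_equal(ps$distance, 2)
  # beyond a vertex: distance to that corner
  ps2 <- point_to_surface_distance(rbind(c(-1, -1, 0)), tri)
  expect_equal(ps2$distance, sqrt(2))
  # surface distance never exceeds vertex distance
  q <- random_points(100, seed = 8, scale = 3)
  m <- subdivided_sphere(2, 2)
  dv <- nearest_neighbors(q, m$vertices)$distance
  ds <- point_to_surface_distance(q, m)$distance
  expect_true(all(ds <= dv + 1e-12))
})
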