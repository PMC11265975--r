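tpl <- make_template_head(3)
graph <- build_edge_graph(tpl)
frame <- attr(tpl, "frame")

test_that("angular sectioning partitions every vertex exactly once, front to back", {
  sec <- partition_sections(tpl, graph, 5, frame)
  expect_equal(sec$n_sections, 6L)
  expect_true(all(sec$section %in% 1:6))
  expect_equal(length(sec$section), nrow(tpl$vertices))
  expect_true(all(table(factor(sec$section, levels = 1:6)) > 0))
  # ordered along the front-over-top-to-back arc
  mean_theta <- tapply(sec$theta, sec$section, mean)
  expect_true(all(diff(mean_theta) > 0))
  expect_true(all(sec$subsection %in% 1:3))

  # independent per-vertex angle-binning oracle
  v <- sweep(tpl$vertices, 2, frame$origin)
  th <- atan2(drop(v %*% frame$up), drop(v %*% frame$front))
  th <- ifelse(th < 0, th + 2 * pi, th)
  width <- diff(range(th)) / 6
  oracle <- pmin(floor((th - min(th)) / width) + 1L, 6L)
  expect_identical(sec$section, as.integer(oracle))
})

test_that("sectioning rejects budgets the mesh cannot support", {
  tiny <- subdivided_sphere(1, 100)
  tiny_g <- build_edge_graph(tiny)
  expect_error(partition_sections(tiny, tiny_g, 40, head_frame()), "empty section")
})

test_that("sampling walks are deterministic in their seed and contiguous within steps", {
  edge_key <- paste(graph$edges[, 1], graph$edges[, 2])
  for (strat in c("side_to_top", "side_to_side", "half_side_to_top",
                  "random_walk")) {
    n_steps <- 6
    sec <- partition_sections(tpl, graph, n_steps, frame)
    t1 <- sample_strategy(tpl, graph, sec, strat, n_steps, seed = 99)
    t2 <- sample_strategy(tpl, graph, sec, strat, n_steps, seed = 99)
    expect_identical(t1, t2)
    t3 <- sample_strategy(tpl, graph, sec, strat, n_steps, seed = 100)
    expect_false(identical(t1$vertex_ids, t3$vertex_ids))

    # within-step contiguity along graph edges
    ids <- t1$vertex_ids
    steps <- t1$step_index
    same_step <- steps[-1] == steps[-length(steps)]
    pairs <- cbind(ids[-length(ids)], ids[-1])[same_step, , drop = FALSE]
    keys <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
    expect_true(all(keys %in% edge_key))

    expect_equal(t1$length, polyline_length(t1$points), tolerance = 1e-9)
  }
})

test_that("a random walk reproduces the seeded uniform-neighbor definition", {
  sec <- partition_sections(tpl, graph, 3, frame)
  traj <- sample_strategy(tpl, graph, sec, "random_walk", 3, seed = 12,
                          target_length = 300)
  # independent stepwise re-run of the generator definition
  e <- graph$edges
  both <- rbind(e, e[, 2:1])
  both <- both[order(both[, 1], both[, 2]), ]
  adj <- split(both[, 2], factor(both[, 1], levels = graph$nodes))
  idx <- which(sec$section == 1L & sec$subsection == 1L & sec$hemisphere >= 0)
  start <- idx[which.max(abs(sec$lateral[idx]))]
  ids <- scalpfit:::with_seed(12, {
    cur <- start
    out <- cur
    total <- 0
    while (total < 300) {
      nbrs <- adj[[cur]]
      nxt <- nbrs[sample.int(length(nbrs), 1)]
      total <- total + sqrt(sum((tpl$vertices[nxt, ] - tpl$vertices[cur, ])^2))
      out <- c(out, nxt)
      cur <- nxt
    }
    unname(out)
  })
  expect_identical(traj$vertex_ids, ids)
})

test_that("half-side walks stay in one hemisphere; geodesic length dominates step chords", {
  sec <- partition_sections(tpl, graph, 7, frame)
  half <- sample_strategy(tpl, graph, sec, "half_side_to_top", 7, seed = 5)
  lat <- drop(sweep(half$points, 2, frame$origin) %*% frame$left)
  expect_true(all(lat >= -1e-9))

  for (strat in c("side_to_top", "side_to_side")) {
    tr <- sample_strategy(tpl, graph, sec, strat, 7, seed = 21)
    for (s in unique(tr$step_index)) {
      p <- tr$points[tr$step_index == s, , drop = FALSE]
      if (nrow(p) < 2) next
      chord <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
      expect_gte(polyline_length(p) + 1e-9, chord)
    }
    expect_lte(tr$geodesic_length, tr$length + 1e-9)
  }
})

test_that("trajectory length grows with the walk budget", {
  lens <- sapply(1:12, function(seed) {
    vapply(c(2, 5, 9, 13), function(ns) {
      sec <- partition_sections(tpl, graph, ns, frame)
      sample_strategy(tpl, graph, sec, "side_to_top", ns, seed = seed)$length
    }, 0)
  })
  rho <- cor(rep(c(2, 5, 9, 13), 12), as.vector(lens), method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("estimated sample normals recover surface orientation from samples alone", {
  sph <- subdivided_sphere(4, 100)
  pts <- sph$vertices
  est <- estimate_sample_normals(pts, 10, c(0, 0, 0))
  ang <- acos(pmin(1, abs(rowSums(est$normals * est$points / 100))))
  expect_lt(max(ang) * 180 / pi, 5)

  # plane z = 0 with the center below: all normals (0, 0, 1)
  grid <- as.matrix(expand.grid(x = seq(0, 9), y = seq(0, 9)))
  plane <- cbind(grid, 0)
  estp <- estimate_sample_normals(plane, 8, c(5, 5, -10))
  expect_equal(estp$normals, matrix(rep(c(0, 0, 1), each = 100), 100),
               tolerance = 1e-9)

  # flipping the head center to the other side flips every normal
  estq <- estimate_sample_normals(plane, 8, c(5, 5, 10))
  expect_equal(estq$normals, -estp$normals, tolerance = 1e-9)

  # collinear neighborhoods fall back to the radial direction, flagged
  line <- cbind(seq(0, 10, length.out = 30), 0, 5)
  estl <- estimate_sample_normals(line, 4, c(0, 0, 0))
  expect_true(all(attr(estl, "fallback")))

  expect_error(estimate_sample_normals(plane[1:5, ], 8, c(0, 0, 0)),
               "more points")
})

test_that("surface coverage counts vertices within the probe radius", {
  sec <- partition_sections(tpl, graph, 4, frame)
  tr <- sample_strategy(tpl, graph, sec, "side_to_top", 4, seed = 2)
  cov <- surface_coverage(tr, tpl, radius = 10)
  d <- nn_oracle(tpl$vertices, tr$points)$distance
  expect_equal(cov, mean(d <= 10))

  all_pts <- tpl$vertices
  expect_equal(surface_coverage(all_pts, tpl, radius = 1e-9), 1.0)
  off <- tpl$vertices + 5
  expect_equal(surface_coverage(off[1, , drop = FALSE], tpl, radius = 1e-12), 0)
  expect_error(surface_coverage(tr, tpl, radius = 0), "positive")
})

test_that("trajectories round-trip through CSV with their sidecar", {
  sec <- partition_sections(tpl, graph, 4, frame)
  tr <- sample_strategy(tpl, graph, sec, "side_to_side", 4, seed = 8)
  path <- file.path(withr::local_tempdir(), "traj.csv")
  write_trajectory_csv(tr, path)
  back <- read_trajectory_csv(path)
  expect_equal(back$points, tr$points, tolerance = 1e-12)
  expect_equal(back$normals, tr$normals, tolerance = 1e-6)
  expect_equal(back$strategy, "side_to_side")
  expect_equal(back$seed, 8)
  expect_equal(back$length, tr$length, tolerance = 1e-9)
})
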