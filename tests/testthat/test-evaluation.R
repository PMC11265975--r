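test_that("position RMSE is the one-sided nearest-neighbor root mean square", {
  p <- random_points(80, seed = 21, scale = 100)
  expect_equal(position_rmse(p, p), 0)
  # every ground-truth point exactly 2 units from its nearest neighbor
  shifted <- p + matrix(c(2, 0, 0), 80, 3, byrow = TRUE)
  expect_equal(position_rmse(p, rbind(shifted, p + 1000)), 2, tolerance = 1e-9)

  gt <- random_points(60, seed = 22)
  rec <- random_points(90, seed = 23)
  or <- nn_oracle(gt, rec)
  expect_equal(position_rmse(gt, rec), sqrt(mean(or$distance^2)),
               tolerance = 1e-12)
  # permutation invariance
  expect_equal(position_rmse(gt[sample(60), ], rec[sample(90), ]),
               position_rmse(gt, rec), tolerance = 1e-12)
  # one-sided: far-away extra reconstruction points never increase it
  far <- rec[1:10, ] + 1e4
  expect_lte(position_rmse(gt, rbind(rec, far)), position_rmse(gt, rec))
})

test_that("Pearson chi-squared matches the direct summation", {
  expect_equal(pearson_chi_squared(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(pearson_chi_squared(c(2, 2), c(1, 1)), 2)
  o <- scalpfit:::with_seed(3, runif(10, 1, 5))
  e <- scalpfit:::with_seed(4, runif(10, 1, 5))
  expect_equal(pearson_chi_squared(o, e), sum((o - e)^2 / e),
               tolerance = 1e-12)
  expect_error(pearson_chi_squared(c(1, 2), c(1, 0)), "positive")
  expect_error(pearson_chi_squared(c(1, 2), c(1)), "length")
})

test_that("binned confidence intervals reproduce a group-by oracle", {
  set.seed(77)
  lengths <- runif(300, 250, 1850)
  rmses <- 3 + 20 * exp(-lengths / 400) + rnorm(300, sd = 0.3)
  b <- binned_confidence_intervals(lengths, rmses, bin_width = 200)
  bin <- floor(lengths / 200)
  for (i in seq_along(b$bin_centers)) {
    sel <- bin == (b$bin_centers[i] - 100) / 200
    expect_equal(b$means[i], mean(rmses[sel]), tolerance = 1e-12)
    expect_equal(b$counts[i], sum(sel))
    expect_equal(b$ci95[i], 1.96 * sd(rmses[sel]) / sqrt(sum(sel)),
                 tolerance = 1e-12)
  }
  # constant values give zero-width intervals
  bc <- binned_confidence_intervals(lengths, rep(4, 300), 200)
  expect_true(all(bc$ci95 == 0))
  # single-point bins are flagged with zero width by convention
  bs <- binned_confidence_intervals(c(250, 450, 451), c(1, 2, 3), 200)
  expect_true(bs$single[1])
  expect_equal(bs$ci95[1], 0)
  expect_warning(binned_confidence_intervals(c(100, 900), c(1, 2), 200),
                 "empty")
})

test_that("the exponential error model recovers exact generating coefficients", {
  x <- seq(200, 1800, by = 50)
  y <- 12 * exp(-0.004 * x) + 2.5
  em <- fit_error_model(x, y, family = "exp_decay")
  expect_equal(unname(coef(em)["a"]), 12, tolerance = 1e-6)
  expect_equal(unname(coef(em)["b"]), -0.004, tolerance = 1e-6)
  expect_equal(unname(coef(em)["c"]), 2.5, tolerance = 1e-6)
  # residual chi-squared reflects only the within-bin curvature of the
  # noiseless curve (binned mean vs value at the bin center)
  expect_lt(em$chi_squared, 0.2)
  expect_equal(predict(em, c(500, 1000)),
               12 * exp(-0.004 * c(500, 1000)) + 2.5, tolerance = 1e-5)
})

test_that("polynomial error models interpolate their own degree exactly", {
  x <- seq(100, 1900, length.out = 40)
  cf <- c(5, -0.004, 2e-6, -3e-10)
  y <- drop(outer(x, 0:3, `^`) %*% cf)
  em <- fit_error_model(x, y, family = "polynomial", degree = 3)
  expect_equal(unname(coef(em)), cf, tolerance = 1e-6)
  fitted <- predict(em, x)
  expect_lt(max(abs(fitted - y)), 1e-8)
  expect_error(fit_error_model(x, y, family = "polynomial", degree = 2),
               "3..7")
})

test_that("richer polynomials never fit the binned means worse on fixed data", {
  # balanced design: equal replicates at each 200 mm bin center
  set.seed(1)
  x <- rep(seq(300, 1700, by = 200), each = 40)
  y <- 14 * exp(-0.0035 * x) + 3 + rnorm(length(x), sd = 0.4)
  chi <- vapply(3:7, function(d)
    fit_error_model(x, y, family = "polynomial", degree = d)$chi_squared, 0)
  expect_true(all(diff(chi) <= 1e-8))
  # exp-decay truth: the decay model beats a constant-mean model
  em <- fit_error_model(x, y, family = "exp_decay")
  b <- binned_confidence_intervals(x, y, 200)
  chi_const <- pearson_chi_squared(b$means, rep(mean(y), length(b$means)))
  expect_lt(em$chi_squared, chi_const)
})

test_that("segment cross-validation is seeded, stratified, and exact on perfect fits", {
  tpl <- make_template_head(3)
  graph <- build_edge_graph(tpl)
  frame <- attr(tpl, "frame")
  sec <- partition_sections(tpl, graph, 8, frame)
  trajs <- lapply(1:3, function(s)
    sample_strategy(tpl, graph, sec, "side_to_top", 8, seed = s))

  # an oracle fit that returns the true surface: all RMSEs are zero
  cv0 <- segment_cross_validation(trajs, function(train) tpl$vertices,
                                  seed = 5, frame = frame)
  expect_equal(cv0$rmse, rep(0, 10))

  fit_centroid <- function(train) train  # echo fit: reconstruction = train set
  cv1 <- segment_cross_validation(trajs, fit_centroid, seed = 9, frame = frame)
  cv2 <- segment_cross_validation(trajs, fit_centroid, seed = 9, frame = frame)
  expect_identical(cv1$rmse, cv2$rmse)
  expect_identical(cv1$held_out, cv2$held_out)
  expect_length(cv1$rmse, 10)
  expect_equal(cv1$n_holdout, 5L)
  expect_true(all(cv1$stratified))

  # every held-out set spans both hemispheres
  pts <- do.call(rbind, lapply(trajs, `[[`, "points"))
  segment <- pmin(ceiling(seq_len(nrow(pts)) / (nrow(pts) / 20)), 20)
  lat <- drop(sweep(pts, 2, frame$origin) %*% frame$left)
  for (held in cv1$held_out) {
    sel <- segment %in% held
    expect_true(any(lat[sel] > 1e-6) && any(lat[sel] < -1e-6))
  }
})

test_that("held-out segments are drawn near-uniformly over many repeats", {
  tpl <- make_template_head(3)
  graph <- build_edge_graph(tpl)
  frame <- attr(tpl, "frame")
  sec <- partition_sections(tpl, graph, 8, frame)
  trajs <- lapply(1:3, function(s)
    sample_strategy(tpl, graph, sec, "side_to_top", 8, seed = s + 10))
  cv <- segment_cross_validation(trajs, function(train) train,
                                 n_repeats = 200, seed = 31, frame = frame)
  freq <- table(factor(unlist(cv$held_out), levels = 1:20))
  # expectation: 200 * 5 / 20 = 50 draws per segment
  expect_true(all(freq > 20))
  expect_true(all(freq < 90))
})
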