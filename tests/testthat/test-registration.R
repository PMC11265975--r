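test_that("one-sided Chamfer matches the brute-force scan in both modes", {
  s <- random_points(150, seed = 1)
  t <- random_points(200, seed = 2)
  or <- nn_oracle(s, t)
  sq <- one_sided_chamfer(s, t, squared = TRUE)
  eu <- one_sided_chamfer(s, t, squared = FALSE)
  expect_equal(sq$cd, mean(or$distance^2), tolerance = 1e-9)
  expect_equal(eu$cd, mean(or$distance), tolerance = 1e-9)
  expect_identical(sq$correspondences, or$index)

  expect_equal(one_sided_chamfer(t[1:50, ], t)$cd, 0)
  single <- rbind(c(0, 0, 0))
  target <- rbind(c(3, 4, 0))
  expect_equal(one_sided_chamfer(single, target, squared = TRUE)$cd, 25)
  expect_equal(one_sided_chamfer(single, target, squared = FALSE)$cd, 5)
})

test_that("normal consistency is a sign-invariant cosine distance in [0, 1]", {
  n <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(normal_consistency(n, n), 0)
  expect_equal(normal_consistency(n, -n), 0)
  orth <- rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  expect_equal(normal_consistency(n, orth), 1)
  expect_error(normal_consistency(n, matrix(0, 3, 3)), "zero-norm")
  a <- random_points(40, seed = 3)
  b <- random_points(40, seed = 4)
  cn <- normal_consistency(a, b)
  expect_gte(cn, 0)
  expect_lte(cn, 1)
})

test_that("the total loss assembles Chamfer, normal, and Frobenius terms", {
  cfg <- fit_config()
  pose0 <- head_pose()
  # w = 0, T = T0, cn = 0: loss is lambda1 * cd alone
  tl <- total_loss(0.37, 0, numeric(3), pose0, pose0, cfg)
  expect_equal(tl$loss, 10 * 0.37)
  expect_equal(tl$reg, 0)
  # all-zero coefficients: zero regardless of inputs
  cfg0 <- fit_config(lambda1 = 0, lambda2 = 0, lambda3 = 0, lambda4 = 0)
  expect_equal(total_loss(5, 3, c(9, 9), head_pose(scale = c(2, 2, 2)),
                          pose0, cfg0)$loss, 0)
  # random inputs vs explicit Frobenius-norm oracle
  w <- scalpfit:::with_seed(6, rnorm(5))
  pose <- head_pose(scale = c(1.1, 0.9, 1.3), rotation = c(0.2, 0.1, -0.3),
                    translation = c(1, 2, 3))
  tl2 <- total_loss(0.5, 0.2, w, pose, pose0, cfg)
  reg_or <- 1 * sqrt(sum(w^2)) +
    1 * sqrt(sum((pose_matrix(pose) - pose_matrix(pose0))^2))
  expect_equal(tl2$reg, reg_or, tolerance = 1e-12)
  expect_equal(tl2$loss, 10 * 0.5 + 1 * 0.2 + reg_or, tolerance = 1e-12)
})

test_that("coarse initialization recovers centroid shifts and beats rejected sign candidates", {
  mod <- toy_model()
  mv <- mod$mean$vertices
  p0 <- coarse_init(mv, mod)
  expect_equal(p0$scale, c(1, 1, 1), tolerance = 1e-6)
  expect_equal(sqrt(sum(p0$rotation^2)), 0, tolerance = 1e-6)
  expect_equal(p0$translation, c(0, 0, 0), tolerance = 1e-4)

  shifted <- mv + matrix(c(10, 0, 0), nrow(mv), 3, byrow = TRUE)
  p1 <- coarse_init(shifted, mod)
  expect_equal(p1$translation, c(10, 0, 0), tolerance = 1e-4)
  expect_lt(sqrt(sum(p1$rotation^2)) * 180 / pi, 0.1)

  pose <- head_pose(scale = c(1.1, 0.9, 1.0), rotation = c(0, 0, pi / 6))
  posed <- apply_pose(pose, mv)
  p2 <- coarse_init(posed, mod)
  cd2 <- one_sided_chamfer(posed, apply_pose(p2, mv))$cd
  expect_lt(cd2, one_sided_chamfer(posed, mv)$cd)
  # the chosen candidate beats all flipped sign assignments
  R2 <- rotation_matrix(p2$rotation)
  for (sg in list(c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))) {
    flip <- head_pose(scale = p2$scale,
                      rotation = axis_angle(R2 %*% diag(sg)),
                      translation = p2$translation)
    expect_lt(cd2, one_sided_chamfer(posed, apply_pose(flip, mv))$cd + 1e-9)
  }

  # degenerate (planar) spread falls back to isotropic scale, flagged
  flat <- cbind(random_points(30, seed = 2)[, 1:2], 0)
  pf <- coarse_init(flat, mod)
  expect_true(attr(pf, "degenerate"))
  expect_equal(pf$scale[1], pf$scale[2])
  expect_error(coarse_init(mv[1:5, ], mod), ">= 10")
})

test_that("analytic objective gradients match central finite differences", {
  mod <- toy_model()
  set.seed(17)
  pts <- mod$mean$vertices[sample(66, 40), ] + matrix(rnorm(120, sd = 1), 40)
  nrm <- estimate_sample_normals(pts, 8, c(0, 0, 0))$normals
  for (case in list(list(corr = "vertex", normals = FALSE, squared = TRUE),
                    list(corr = "surface", normals = FALSE, squared = TRUE),
                    list(corr = "surface", normals = TRUE, squared = TRUE),
                    list(corr = "surface", normals = FALSE, squared = FALSE))) {
    cfg <- fit_config(use_normals = case$normals, squared = case$squared,
                      correspondence = case$corr)
    vf <- scalpfit:::vertex_face_csr(mod$mean$faces, 66)
    data <- list(X = pts * 0.1, Xn = nrm, mu = mod$mean$vertices * 0.1,
                 V = mod$eigenvectors, e = mod$eigenvalues * 0.1,
                 faces = mod$mean$faces, vf_ptr = vf$ptr, vf_idx = vf$idx,
                 T0 = pose_matrix(head_pose(translation = c(0.1, 0, 0))),
                 k = 3L, config = cfg)
    par <- c(0.4, -0.3, 0.2, log(c(1.04, 0.96, 1.02)),
             c(0.06, -0.04, 0.09), c(0.15, -0.12, 0.07))
    lag <- scalpfit:::loss_and_grad
    first <- lag(par, data)
    corr <- first$corr
    verts <- data$mu + scalpfit:::unflatten_vertices(
      data$V %*% (par[1:3] * data$e))
    n0 <- scalpfit:::vnormals_quick(verts, data$faces)
    an <- lag(par, data, corr = corr, n0 = n0)
    fd <- vapply(seq_along(par), function(i) {
      h <- 1e-6
      pp <- par; pp[i] <- pp[i] + h
      pm <- par; pm[i] <- pm[i] - h
      (lag(pp, data, corr = corr, n0 = n0)$loss -
         lag(pm, data, corr = corr, n0 = n0)$loss) / (2 * h)
    }, 0)
    expect_equal(an$grad, fd, tolerance = 1e-4)
  }
})

test_that("the joint fit is deterministic and honors a dominant weight penalty", {
  mod <- toy_model()
  pose <- head_pose(scale = c(1.02, 0.98, 1.0), rotation = c(0.02, 0, -0.03),
                    translation = c(5, 2, -3))
  subj <- make_subject(mod, c(0.8, -0.5, 0.3), pose)
  set.seed(3)
  pts <- subj$mesh$vertices[sample(66, 50), ]
  cfg <- fit_config(max_iter = 300)
  f1 <- fit_scalp(mod, pts, config = cfg)
  f2 <- fit_scalp(mod, pts, config = cfg)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(f1$pose, f2$pose)

  # lambda3 >> all: weights are crushed to zero, pose stays near pose0
  posed_mean <- apply_pose(pose, mod$mean)
  cfg_big <- fit_config(lambda3 = 1e5, max_iter = 400)
  fbig <- fit_scalp(mod, posed_mean$vertices, config = cfg_big)
  expect_lt(sqrt(sum(coef(fbig)^2)), 1e-4)
})

test_that("the loss trend is non-increasing after burn-in", {
  mod <- toy_model()
  subj <- make_subject(mod, c(0.6, -0.4, 0.2),
                       head_pose(translation = c(8, -5, 3)))
  set.seed(9)
  pts <- subj$mesh$vertices[sample(66, 45), ]
  fit <- fit_scalp(mod, pts, config = fit_config(max_iter = 600))
  h <- fit$loss_history$total
  burn <- h[-(1:10)]
  # transient Adam oscillations allowed; the envelope must descend
  expect_true(all(diff(burn) < 0.05 * abs(burn[-length(burn)])))
  expect_lt(tail(cummin(burn), 1), burn[1])
  expect_lt(tail(burn, 1), h[1])
})

test_that("fits are equivariant under rigid motion of the samples", {
  mod <- toy_model()
  subj <- make_subject(mod, c(0.7, -0.3, 0.4),
                       head_pose(translation = c(4, 1, -2)))
  set.seed(23)
  pts <- subj$mesh$vertices[sample(66, 55), ]
  cfg <- fit_config(max_iter = 2500, patience = 300, min_delta = 1e-9)
  p0 <- coarse_init(pts, mod)
  f1 <- fit_scalp(mod, pts, pose0 = p0, config = cfg)

  Rex <- rotation_matrix(c(0.1, 0.25, -0.15))
  tex <- c(30, -12, 20)
  pts2 <- pts %*% t(Rex) + matrix(tex, nrow(pts), 3, byrow = TRUE)
  R0 <- rotation_matrix(p0$rotation)
  p0b <- head_pose(scale = p0$scale, rotation = axis_angle(Rex %*% R0),
                   translation = drop(Rex %*% p0$translation) + tex)
  f2 <- fit_scalp(mod, pts2, pose0 = p0b, config = cfg)
  expect_equal(coef(f2), coef(f1), tolerance = 1e-3)
  # final poses are conjugate: T2 ~ Rigid o T1
  T1 <- pose_matrix(f1$pose)
  Rig <- diag(4); Rig[1:3, 1:3] <- Rex; Rig[1:3, 4] <- tex
  expect_equal(pose_matrix(f2$pose), Rig %*% T1, tolerance = 1e-2)
})

test_that("normal-free configurations ignore supplied normals", {
  mod <- toy_model()
  subj <- make_subject(mod, c(0.5, 0.2, -0.1), head_pose())
  set.seed(31)
  pts <- subj$mesh$vertices[sample(66, 40), ]
  cfg <- fit_config(lambda2 = 0, use_normals = FALSE, max_iter = 200)
  fa <- fit_scalp(mod, pts, config = cfg)
  fake <- matrix(rep(c(1, 0, 0), each = 40), 40)
  fb <- fit_scalp(mod, pts, config = cfg, sample_normals = fake)
  expect_identical(coef(fa), coef(fb))
  expect_identical(fa$pose, fb$pose)
})

test_that("the fit result is internally consistent and its methods work", {
  mod <- toy_model()
  subj <- make_subject(mod, c(0.4, -0.2, 0.1), head_pose(translation = c(2, 2, 2)))
  set.seed(41)
  pts <- subj$mesh$vertices[sample(66, 35), ]
  fit <- fit_scalp(mod, pts, config = fit_config(max_iter = 150))
  # reconstructed == pose applied to synthesize(model, weights)
  rebuilt <- apply_pose(fit$pose, synthesize(mod, coef(fit)))
  expect_equal(fit$reconstructed$vertices, rebuilt$vertices, tolerance = 1e-9)
  expect_equal(length(residuals(fit)), 35)
  expect_s3_class(fitted(fit), "trimesh")
  pred <- predict(fit, pts[1:5, ])
  expect_equal(dim(pred), c(5, 3))
  expect_output(print(fit), "Joint scalp-surface fit")
  expect_output(print(summary(fit)), "sample residuals")
})
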