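test_that("profile sampling has the stated length, normalization and zeros", {
  img <- matrix(100, 40, 40)
  p <- sample_profile(img, c(20, 20), c(0, 1), k = 6)
  expect_length(p, 13)
  expect_equal(p, rep(0, 13))  # constant image: zero gradient profile

  # ideal vertical step crossed along the normal: peak at the center sample
  step <- cbind(matrix(0, 41, 20), matrix(200, 41, 21))
  pr <- sample_profile(step, c(20.5, 21), c(1, 0), k = 5)
  expect_length(pr, 11)
  expect_equal(which.max(pr), 6)
  expect_equal(sum(abs(pr)), 1)

  # clipping at borders still yields 2k+1 samples
  expect_length(sample_profile(step, c(2, 2), c(1, 0), k = 8), 17)
  expect_error(sample_profile(img, c(5, 5), c(0, 0), 4), "zero")
})

test_that("profile models have one entry per landmark with sane covariance", {
  r <- render_radiograph(synthetic_spec(seed = 11, noise_sd = 0))
  imgs <- rep(list(r$image), 3)
  shapes <- rep(list(r$truth$shapes$C4), 3)
  pm <- build_profile_models(imgs, shapes, k = 5)
  expect_equal(nrow(pm$means), 12)
  expect_length(pm$covs, 12)
  for (S in pm$covs) {
    expect_true(isSymmetric(S, tol = 1e-12))
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  expect_error(build_profile_models(imgs, list(shapes[[1]], shapes[[2]][1:6, ],
                                               shapes[[3]]), 5),
               "inconsistent")
})

test_that("mahalanobis cost matches its definition", {
  m <- rep(0, 4)
  expect_equal(mahalanobis_cost(m, m, diag(4)), 0)
  g <- c(1, 2, -1, 0.5)
  expect_equal(mahalanobis_cost(g, m, diag(4)), sum(g^2))  # identity cov
  set.seed(161)
  S <- crossprod(matrix(rnorm(16), 4, 4)) + diag(4)
  d <- rnorm(4)
  expect_equal(mahalanobis_cost(d + m, m, S),
               as.numeric(t(d) %*% solve(S) %*% d))
})

test_that("a search step is a fixed point at the optimum and restores offsets", {
  r <- render_radiograph(synthetic_spec(seed = 13, noise_sd = 0))
  sm <- default_vertebra_model()
  pm <- build_profile_models(
    rep(list(r$image), 5),
    unname(r$truth$shapes), k = 6)
  truth <- r$truth$shapes$C5
  pr <- project_shape(sm, truth)
  truth_reg <- generate_shape(sm, pr$b, pr$pose)  # truth in model space

  stepped <- asm_search_step(r$image, truth_reg, sm, pm)
  expect_lt(mean(sqrt(rowSums((stepped - truth_reg)^2))), 0.75)

  # displaced init moves back toward the boundary
  shifted <- truth_reg + matrix(c(3, 0), nrow(truth_reg), 2, byrow = TRUE)
  back <- asm_search_step(r$image, shifted, sm, pm)
  e0 <- mean(point_to_line_distance(truth, shifted, closed = TRUE))
  e1 <- mean(point_to_line_distance(truth, back, closed = TRUE))
  expect_lt(e1, e0)

  # constrained coefficients stay within 3 SD
  prb <- project_shape(sm, back, b_limit = Inf)
  expect_true(all(abs(prb$b) <= 3 * sqrt(sm$variances) + 1e-6))
})

test_that("segmentation converges and respects the iteration contract", {
  r <- render_radiograph(synthetic_spec(seed = 17, noise_sd = 0))
  sm <- default_vertebra_model()
  pm <- default_profile_model()
  truth <- r$truth$shapes$C4
  pr <- project_shape(sm, truth)
  init <- generate_shape(sm, pr$b, pr$pose)

  # max_iter = 0 returns the init unconverged
  f0 <- segment_vertebra(r$image, init, sm, pm, max_iter = 0)
  expect_equal(f0$final_shape, init, ignore_attr = TRUE)
  expect_false(f0$converged)
  expect_equal(f0$iterations, 0)

  # truth-initialized fit converges immediately with negligible movement
  f1 <- segment_vertebra(r$image, init, sm, pm)
  expect_true(f1$converged)
  expect_lte(f1$iterations, 3)
  expect_lt(mean(point_to_line_distance(truth, f1$final_shape,
                                        closed = TRUE)), 1)

  # perturbed init improves
  f2 <- segment_vertebra(r$image,
                         init + matrix(c(-4, 2), nrow(init), 2, byrow = TRUE),
                         sm, pm)
  e_init <- mean(point_to_line_distance(truth, init + matrix(c(-4, 2),
                                                             nrow(init), 2,
                                                             byrow = TRUE),
                                        closed = TRUE))
  e_fin <- mean(point_to_line_distance(truth, f2$final_shape, closed = TRUE))
  expect_lt(e_fin, e_init)

  # deterministic given identical inputs
  f3 <- segment_vertebra(r$image, init, sm, pm)
  expect_identical(f1$final_shape, f3$final_shape)
})
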