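square_shape <- function() cbind(x = c(0, 2, 2, 0), y = c(0, 0, 2, 2))

test_that("pairwise Procrustes recovers exact similarity relations", {
  s <- square_shape()
  self <- procrustes_pair(s, s)
  expect_equal(self$pose$scale, 1)
  expect_equal(self$pose$rotation, 0)
  expect_equal(self$residual, 0, tolerance = 1e-20)

  rot <- apply_pose(s, pose_params(1.5, 30 * pi / 180, c(3, -2)))
  rec <- procrustes_pair(s, rot)
  expect_equal(rec$pose$scale, 1.5)
  expect_equal(rec$pose$rotation, 30 * pi / 180)
  expect_lt(rec$residual, 1e-18)

  expect_error(procrustes_pair(cbind(rep(1, 4), rep(2, 4)), s), "degenerate")
})

test_that("pairwise Procrustes residual beats 1000 random similarity poses", {
  set.seed(111)
  a <- matrix(rnorm(16), 8, 2)
  b <- matrix(rnorm(16), 8, 2)
  best <- procrustes_pair(a, b)$residual
  rand <- replicate(1000, {
    p <- pose_params(runif(1, 0.2, 3), runif(1, -pi, pi), rnorm(2, sd = 2))
    sum((apply_pose(a, p) - b)^2)
  })
  expect_lte(best, min(rand))
})

test_that("set alignment collapses similarity-transformed copies", {
  s <- square_shape()
  set.seed(121)
  copies <- lapply(1:6, function(i) {
    apply_pose(s, pose_params(runif(1, 0.5, 2), runif(1, -pi / 2, pi / 2),
                              rnorm(2, sd = 5)))
  })
  al <- procrustes_align_set(copies)
  for (a in al$aligned) {
    expect_lt(procrustes_pair(a, al$mean)$residual, 1e-16)
  }

  ident <- procrustes_align_set(list(s, s, s))
  expect_equal(ident$iterations, 1)
})

test_that("PCA model honours the variance fraction and degenerate cases", {
  s <- square_shape()
  # identical shapes: zero variance, t = 0, generator returns the mean
  m0 <- build_pca_model(list(s, s, s))
  expect_equal(m0$t, 0)
  expect_equal(generate_shape(m0), unname(s), ignore_attr = TRUE)

  # rank-1 variation along a known direction
  v <- c(1, -1, 0, 0, 0, 0, 1, -1) / 2
  shapes <- lapply(c(-2, -1, 1, 2), function(d) {
    s + matrix(v * d * 0.1, 4, 2)
  })
  m1 <- build_pca_model(shapes, 0.99)
  expect_equal(m1$t, 1)
  expect_equal(abs(sum(m1$modes[, 1] * v / sqrt(sum(v^2)))), 1,
               tolerance = 1e-9)

  expect_error(build_pca_model(shapes, 0), "variance_fraction")
})

test_that("generate/project round trip preserves in-range coefficients", {
  model <- synthetic_two_mode_model()
  expect_equal(generate_shape(model, c(0, 0)),
               shape_from_vector(model$mean_shape), ignore_attr = TRUE)

  set.seed(131)
  for (i in 1:10) {
    b <- rnorm(2, 0, sqrt(model$variances))
    b <- pmin(pmax(b, -2.5 * sqrt(model$variances)), 2.5 * sqrt(model$variances))
    pose <- pose_params(runif(1, 0.8, 1.2), runif(1, -0.3, 0.3), rnorm(2))
    sh <- generate_shape(model, b, pose)
    pr <- project_shape(model, sh)
    expect_equal(pr$b, b, tolerance = 1e-6)
    expect_equal(pr$pose$scale, pose$scale, tolerance = 1e-6)
  }

  # out-of-range coefficients are clamped to 3 SD
  big <- generate_shape(model, c(5 * sqrt(model$variances[1]), 0))
  prb <- project_shape(model, big)
  expect_equal(prb$b[1], 3 * sqrt(model$variances[1]), tolerance = 1e-6)

  expect_error(generate_shape(model, c(1, 2, 3)), "mode count")
})

test_that("modes are orthonormal and variances descending", {
  shapes <- synthetic_vertebra_shapes(40, seed = 7)
  al <- procrustes_align_set(shapes)
  m <- build_pca_model(al$aligned, 0.98)
  expect_gt(m$t, 0)
  expect_equal(crossprod(m$modes), diag(m$t), tolerance = 1e-9)
  expect_true(all(diff(m$variances) <= 1e-12))
})

test_that("landmark and model serialization round trip", {
  shapes <- synthetic_vertebra_shapes(3, seed = 3)
  csv <- tempfile(fileext = ".csv")
  write_landmarks(shapes, csv)
  back <- read_landmarks(csv)
  expect_length(back, 3)
  expect_equal(unname(back[[1]]), unname(shapes[[1]]))

  model <- synthetic_two_mode_model()
  js <- tempfile(fileext = ".json")
  write_shape_model(model, js)
  m2 <- read_shape_model(js)
  expect_equal(m2$mean_shape, model$mean_shape)
  expect_equal(m2$modes, model$modes, ignore_attr = TRUE)
  expect_equal(m2$variances, model$variances)
})
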