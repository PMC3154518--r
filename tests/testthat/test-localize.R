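test_that("curvature model building recovers congruent training shapes", {
  samples <- synthetic_curvature_samples(6, seed = 9)
  # identical samples: mean congruent to the sample
  cm0 <- build_curvature_model(list(samples[[1]], samples[[1]]))
  expect_lt(procrustes_pair(cm0$mean_shape, samples[[1]])$residual, 1e-12)

  # similarity-transformed copies of one sequence
  copies <- lapply(1:4, function(i) {
    apply_pose(samples[[1]], pose_params(0.5 + 0.3 * i, 0.1 * i, c(i, -i)))
  })
  cmc <- build_curvature_model(copies)
  expect_lt(procrustes_pair(cmc$mean_shape, samples[[1]])$residual, 1e-10)

  expect_error(build_curvature_model(list(samples[[1]],
                                          samples[[1]][1:6, ])),
               "inconsistent")
})

test_that("ROI alignment is exact at the anchors and shape-preserving", {
  cm <- default_curvature_model()
  n <- cm$n_landmarks
  # clicks at the model's own endpoints: identity placement
  ident <- align_model_to_roi(cm, roi_clicks(cm$mean_shape[1, ],
                                             cm$mean_shape[n, ]))
  expect_equal(ident, cm$mean_shape, ignore_attr = TRUE, tolerance = 1e-12)

  # rotated + scaled clicks: all landmarks follow the same similarity
  z <- complex(real = cm$mean_shape[, 1], imaginary = cm$mean_shape[, 2])
  a <- 2 * exp(1i * pi / 2)
  w <- a * z + (100 + 50i)
  pos <- align_model_to_roi(cm, roi_clicks(c(Re(w[1]), Im(w[1])),
                                           c(Re(w[n]), Im(w[n]))))
  expect_equal(pos, cbind(x = Re(w), y = Im(w)), ignore_attr = TRUE,
               tolerance = 1e-9)

  # random clicks: endpoints exact, interior geometry preserved
  set.seed(141)
  for (i in 1:5) {
    ck <- roi_clicks(runif(2, 50, 100), runif(2, 300, 400))
    pos <- align_model_to_roi(cm, ck)
    expect_equal(unname(pos[1, ]), ck$top, tolerance = 1e-10)
    expect_equal(unname(pos[n, ]), ck$bottom, tolerance = 1e-10)
    # length ratios preserved under similarity
    d_model <- dist(cm$mean_shape); d_pos <- dist(pos)
    expect_equal(as.vector(d_pos / d_model),
                 rep((d_pos / d_model)[1], length(d_model)),
                 tolerance = 1e-9)
  }
  expect_error(roi_clicks(c(1, 1), c(1, 1)), "distinct")
})

test_that("corner matching assigns nearest corners under the ordering rule", {
  cm <- default_curvature_model()
  ck <- roi_clicks(c(200, 100), c(250, 420))
  pos <- align_model_to_roi(cm, ck)

  # corners exactly at the landmarks: perfect assignment
  corners <- data.frame(x = pos[, 1], y = pos[, 2])
  an <- match_corners(pos, corners, ck)
  expect_true(all(an$matched))
  expect_equal(an$x, unname(pos[, 1]))

  # a distant spurious corner is never selected
  corners2 <- rbind(corners, data.frame(x = 500, y = 50))
  an2 <- match_corners(pos, corners2, ck)
  expect_equal(an2[, c("x", "y")], an[, c("x", "y")], ignore_attr = TRUE)

  # matched positions are a subset of the corner set and monotone along
  # the click axis
  set.seed(151)
  jit <- corners
  jit$x <- jit$x + rnorm(10); jit$y <- jit$y + rnorm(10)
  an3 <- match_corners(pos, jit, ck)
  expect_true(all(paste(an3$x, an3$y) %in% paste(jit$x, jit$y)))
  u <- (ck$bottom - ck$top); u <- u / sqrt(sum(u^2))
  proj <- (an3$x - ck$top[1]) * u[1] + (an3$y - ck$top[2]) * u[2]
  expect_true(all(diff(proj) > 0))

  # landmark with no corner in range falls back to the model position
  far <- data.frame(x = pos[1:2, 1], y = pos[1:2, 2])
  an4 <- match_corners(pos, far, ck)
  expect_false(all(an4$matched))
  expect_equal(an4$x[!an4$matched], unname(pos[!an4$matched, 1]))

  expect_error(match_corners(pos, corners[0, ], ck), "empty")
})

test_that("per-vertebra initialization pins the anterior corners", {
  sm <- default_vertebra_model()
  r <- render_radiograph(synthetic_spec(seed = 3, noise_sd = 0))
  pos <- align_model_to_roi(default_curvature_model(), r$truth$clicks)
  gt <- r$truth$anterior_landmarks
  an <- match_corners(pos, data.frame(x = gt[, 1], y = gt[, 2]),
                      r$truth$clicks)
  inits <- init_vertebra_shapes(an, sm, c(1, 10))
  expect_named(inits, paste0("C", 3:7))
  for (i in seq_along(inits)) {
    expect_equal(unname(inits[[i]][1, ]), unname(gt[2 * i - 1, ]),
                 tolerance = 1e-9)
    expect_equal(unname(inits[[i]][10, ]), unname(gt[2 * i, ]),
                 tolerance = 1e-9)
  }
})
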