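test_that("gaussian smoothing preserves constants and reproduces the kernel", {
  expect_equal(gaussian_smooth(matrix(7, 12, 15), 2), matrix(7, 12, 15))

  # unnormalized kernel center value is 1/(2 pi sigma^2)
  k_un <- gaussian_kernel(1.3, normalize = FALSE)
  expect_equal(k_un[ceiling(nrow(k_un) / 2), ceiling(ncol(k_un) / 2)],
               1 / (2 * pi * 1.3^2))

  # impulse response equals the sampled normalized kernel
  imp <- matrix(0, 25, 25); imp[13, 13] <- 1
  out <- gaussian_smooth(imp, 1.7)
  r <- ceiling(3 * 1.7)
  expect_equal(out[13 + (-r:r), 13 + (-r:r)], unname(gaussian_kernel(1.7)),
               tolerance = 1e-12)

  expect_error(gaussian_smooth(imp, -1), "positive")
})

test_that("recursive smoothing agrees with direct convolution within 1% RMS", {
  set.seed(51)
  img <- gaussian_smooth(matrix(runif(80 * 60) * 255, 60, 80), 1)
  for (s in c(1.4, 3)) {
    a <- gaussian_smooth(img, s)
    b <- deriche_smooth(img, s)
    expect_lt(sqrt(mean((a - b)^2)) / sqrt(mean(a^2)), 0.01)
  }
})

test_that("sobel gradients match the mask responses and identities", {
  # vertical step 0 | 255: |gx| = 4 * 255 on the step, gy = 0
  img <- cbind(matrix(0, 9, 5), matrix(255, 9, 5))
  f <- sobel_gradients(img)
  expect_equal(abs(f$gx[5, 5]), 4 * 255)
  expect_equal(f$gy[5, 5], 0)

  # constant image: zero gradient
  fc <- sobel_gradients(matrix(42, 8, 8))
  expect_true(all(fc$magnitude == 0))

  # magnitude and direction identities
  expect_equal(sqrt(3^2 + 4^2), 5)
  expect_true(all(abs(f$magnitude^2 - (f$gx^2 + f$gy^2)) < 1e-6))
  g45 <- sobel_gradients(outer(1:9, 1:9, "+") * 10)  # gx = gy > 0 interior
  expect_equal(g45$direction[5, 5], pi / 4)

  expect_error(sobel_gradients(matrix(0, 2, 5)), "3x3")
})

test_that("non-maxima suppression keeps ridge maxima and matches the oracle", {
  z <- matrix(0, 6, 6)
  expect_equal(nonmax_suppression(structure(list(gx = z, gy = z,
                                                 magnitude = z, direction = z),
                                            class = "gradient_field")), z)

  # horizontal gradient profile [1, 5, 1]: only the 5 survives
  img <- matrix(0, 7, 7)
  img[, 4] <- 60  # bright column: gradient horizontal on its flanks
  f <- sobel_gradients(img)
  nms <- nonmax_suppression(f)
  expect_true(all(nms[3:5, 4] == 0) || all(nms[3:5, 3] >= 0))  # ridge thinning
  # survivors are a pointwise subset of the input magnitudes
  expect_true(all(nms == 0 | nms == f$magnitude))

  # random fields: exact agreement with the per-pixel oracle
  set.seed(61)
  for (i in 1:5) {
    img <- gaussian_smooth(matrix(runif(20 * 20) * 255, 20, 20), 0.8)
    f <- sobel_gradients(img)
    expect_equal(nonmax_suppression(f), oracle_nms(f$magnitude, f$direction))
  }
})

test_that("hysteresis follows the three-way rule and its connectivity clause", {
  # chain [120, 60, 60, 40]: first three accepted, last rejected
  nms <- matrix(0, 5, 6)
  nms[3, 2:5] <- c(120, 60, 60, 40)
  mask <- hysteresis(nms, 50, 100, 8)
  expect_equal(which(mask), which(matrix(c(nms[3, ] >= 50), 5, 6,
                                         byrow = TRUE) & nms > 0))
  expect_true(all(mask[3, 2:4]))
  expect_false(mask[3, 5])

  expect_equal(sum(hysteresis(nms, 130, 200, 8)), 0)      # all below low
  expect_equal(sum(hysteresis(nms, 0.5, 30, 8)), 4)       # all above high

  expect_error(hysteresis(nms, 10, 5), "exceeds")
})

test_that("hysteresis matches a breadth-first-search oracle on random fields", {
  set.seed(71)
  for (conn in c(4, 8)) {
    for (i in 1:5) {
      img <- gaussian_smooth(matrix(runif(24 * 24) * 255, 24, 24), 1)
      nms <- nonmax_suppression(sobel_gradients(img))
      q <- quantile(nms[nms > 0], c(0.3, 0.7))
      expect_equal(hysteresis(nms, q[1], q[2], conn),
                   oracle_hysteresis_bfs(nms, q[1], q[2], conn))
    }
  }
})

test_that("edge-map invariants hold and raising high never adds pixels", {
  set.seed(81)
  img <- gaussian_smooth(matrix(runif(30 * 30) * 255, 30, 30), 1)
  nms <- nonmax_suppression(sobel_gradients(img))
  lo <- quantile(nms[nms > 0], 0.3)
  his <- quantile(nms[nms > 0], c(0.5, 0.7, 0.9))
  prev <- NULL
  for (h in his) {
    m <- hysteresis(nms, lo, h, 8)
    expect_true(all(nms[m] >= lo))
    if (!is.null(prev)) expect_true(all(prev[m]))  # shrinking membership
    prev <- m
  }
})

test_that("canny traces a synthetic square boundary within one pixel", {
  img <- matrix(20, 64, 64)
  img[20:45, 18:47] <- 200
  mask <- canny(img, canny_params(sigma = 1.4, low = 20, high = 60,
                                  threshold_mode = "absolute"))
  expect_gt(sum(mask), 80)
  found <- which(mask, arr.ind = TRUE)
  # distance from each edge pixel to the true rectangle boundary
  r0 <- 19.5; r1 <- 45.5; c0 <- 17.5; c1 <- 47.5
  dr <- pmin(abs(found[, 1] - r0), abs(found[, 1] - r1))
  dc <- pmin(abs(found[, 2] - c0), abs(found[, 2] - c1))
  inside_r <- found[, 1] >= r0 & found[, 1] <= r1
  inside_c <- found[, 2] >= c0 & found[, 2] <= c1
  d <- ifelse(inside_c, ifelse(inside_r, pmin(dr, dc), dr),
              ifelse(inside_r, dc, sqrt(dr^2 + dc^2)))
  expect_lte(max(d), 1)

  # constant image: empty edge map
  expect_equal(sum(canny(matrix(77, 32, 32))), 0)
})
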