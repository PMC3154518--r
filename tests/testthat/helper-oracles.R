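# Independent oracle implementations: literal transcriptions of the rules
# the package operations implement, written against the rule statements and
# kept free of package internals.

# histogram clipping by brute-force iterative redistribution: cap, spread
# the excess uniformly, repeat while any bin still exceeds the cap (up to a
# pass limit mirroring the implementation's single residue sweep is NOT
# used here: the loop runs to a fixed point, used only to justify bounds)
oracle_clip_bounds <- function(hist, limit) {
  n <- length(hist)
  h <- hist
  for (pass in 1:100) {
    over <- pmax(h - limit, 0)
    if (sum(over) < 1e-12) break
    h <- pmin(h, limit) + sum(over) / n
  }
  h
}

# per-pixel bilinear CLAHE blend: for each pixel find the 4 surrounding
# region centers, the weights x, y, and blend the four transforms
oracle_clahe_pixel <- function(img, grid) {
  p <- grid$params; g <- grid$grid
  nr <- nrow(img); nc <- ncol(img)
  n_bins <- p$n_bins
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      bin <- min(max(floor(img[r, c] / (grid$max_level + 1e-9) * n_bins) + 1, 1),
                 n_bins)
      ty <- max(1, min(sum(g$row_centers <= r), p$tiles_y - 1))
      tx <- max(1, min(sum(g$col_centers <= c), p$tiles_x - 1))
      if (p$tiles_y == 1) { ty <- 1; y <- 0 } else {
        y <- (r - g$row_centers[ty]) / (g$row_centers[ty + 1] - g$row_centers[ty])
        y <- min(max(y, 0), 1)
      }
      if (p$tiles_x == 1) { tx <- 1; x <- 0 } else {
        x <- (c - g$col_centers[tx]) / (g$col_centers[tx + 1] - g$col_centers[tx])
        x <- min(max(x, 0), 1)
      }
      tx2 <- min(tx + (p$tiles_x > 1), p$tiles_x)
      ty2 <- min(ty + (p$tiles_y > 1), p$tiles_y)
      Tr <- function(tyy, txx) grid$transforms[(tyy - 1) * p$tiles_x + txx, bin]
      out[r, c] <- (1 - y) * ((1 - x) * Tr(ty, tx) + x * Tr(ty, tx2)) +
        y * ((1 - x) * Tr(ty2, tx) + x * Tr(ty2, tx2))
    }
  }
  out
}

# per-pixel non-maxima suppression over the 4 quantized directions
oracle_nms <- function(mag, theta) {
  nr <- nrow(mag); nc <- ncol(mag)
  out <- matrix(0, nr, nc)
  offs <- list(c(0, 1), c(1, 1), c(1, 0), c(-1, 1))
  for (r in 2:(nr - 1)) {
    for (c in 2:(nc - 1)) {
      if (mag[r, c] <= 0) next
      s <- round((theta[r, c] %% pi) / (pi / 4)) %% 4
      o <- offs[[s + 1]]
      n1 <- mag[r + o[1], c + o[2]]
      n2 <- mag[r - o[1], c - o[2]]
      if (mag[r, c] >= n1 && mag[r, c] >= n2) out[r, c] <- mag[r, c]
    }
  }
  out
}

# hysteresis by breadth-first search from the above-high pixels
oracle_hysteresis_bfs <- function(nms, low, high, connectivity = 8) {
  nr <- nrow(nms); nc <- ncol(nms)
  cand <- nms >= low & nms > 0
  acc <- matrix(FALSE, nr, nc)
  queue <- which(nms > high & cand)
  acc[queue] <- TRUE
  offs <- if (connectivity == 4) {
    list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))
  } else {
    list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0),
         c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  }
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    r <- (i - 1) %% nr + 1; c <- (i - 1) %/% nr + 1
    for (o in offs) {
      rr <- r + o[1]; cc <- c + o[2]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
          cand[rr, cc] && !acc[rr, cc]) {
        acc[rr, cc] <- TRUE
        queue <- c(queue, (cc - 1) * nr + rr)
      }
    }
  }
  acc
}

# literal recursive transcription of the polygonal-approximation rule:
# if the farthest point's distance d <= eps remove all interior points,
# if d > eps recurse on the two sub-polylines, stop when no interior point
oracle_dp_indices <- function(pts, eps) {
  seg_dist <- function(p, a, b) {
    d <- b - a; l2 <- sum(d^2)
    if (l2 == 0) return(sqrt(sum((p - a)^2)))
    t <- min(max(sum((p - a) * d) / l2, 0), 1)
    sqrt(sum((p - (a + t * d))^2))
  }
  rec <- function(i, j) {
    if (j - i < 2) return(c(i, j))
    ds <- sapply((i + 1):(j - 1), function(k) seg_dist(pts[k, ], pts[i, ], pts[j, ]))
    kmax <- i + which.max(ds)
    if (max(ds) > eps) {
      sort(unique(c(rec(i, kmax), rec(kmax, j))))
    } else {
      c(i, j)
    }
  }
  rec(1, nrow(pts))
}

# literal transcription of the 3-SD success/failure trimming rule
oracle_trim <- function(errors) {
  success <- seq_along(errors)
  repeat {
    m <- mean(errors[success]); s <- stats::sd(errors[success])
    if (!is.finite(s)) s <- 0
    drop <- success[errors[success] > m + 3 * s]
    if (!length(drop) || length(success) - length(drop) < 2) break
    success <- setdiff(success, drop)
  }
  setdiff(seq_along(errors), success)
}

# dense-sampling minimum distance to the interpolating spline (10^4 points)
oracle_spline_distance <- function(gold, fitted, closed = FALSE,
                                   n_dense = 1e4) {
  pts <- fitted
  if (closed) pts <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(pts)^2))
  tk <- c(0, cumsum(seg))
  fx <- stats::splinefun(tk, pts[, 1], method = "natural")
  fy <- stats::splinefun(tk, pts[, 2], method = "natural")
  tt <- seq(0, max(tk), length.out = n_dense)
  sx <- fx(tt); sy <- fy(tt)
  apply(gold, 1, function(p) sqrt(min((sx - p[1])^2 + (sy - p[2])^2)))
}
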