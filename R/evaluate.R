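#' Point-to-line segmentation error
#'
#' For each landmark of the gold-standard contour, the minimum distance to
#' the interpolating spline through the fitted contour's landmarks: a
#' natural cubic spline in each coordinate, parameterized by cumulative
#' chord length. The minimum is located by dense sampling
#' (\code{samples_per_segment} points per landmark interval) followed by
#' local refinement, which realizes the perpendicular drop wherever the
#' foot of the perpendicular exists.
#'
#' @param gold n x 2 gold-standard landmark matrix.
#' @param fitted m x 2 fitted landmark matrix (m >= 2).
#' @param closed Treat the fitted contour as a closed loop.
#' @param samples_per_segment Dense-search resolution.
#' @return Numeric vector of per-landmark distances (pixels).
#' @export
point_to_line_distance <- function(gold, fitted, closed = FALSE,
                                   samples_per_segment = 1000) {
  stopifnot(is.matrix(gold), is.matrix(fitted))
  if (nrow(fitted) < 2) stop("fitted contour needs at least 2 landmarks")
  pts <- fitted
  if (closed) pts <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(pts)^2))
  if (all(seg == 0)) stop("degenerate fitted contour: zero length")
  t_knots <- c(0, cumsum(seg))
  keep <- c(TRUE, seg > 0)  # drop repeated knots
  t_knots <- t_knots[keep]
  px <- pts[keep, 1]; py <- pts[keep, 2]
  fx <- stats::splinefun(t_knots, px, method = "natural")
  fy <- stats::splinefun(t_knots, py, method = "natural")
  tt <- seq(0, max(t_knots),
            length.out = samples_per_segment * (length(t_knots) - 1) + 1)
  sx <- fx(tt); sy <- fy(tt)
  dt <- tt[2] - tt[1]
  vapply(seq_len(nrow(gold)), function(i) {
    d2 <- (sx - gold[i, 1])^2 + (sy - gold[i, 2])^2
    j <- which.min(d2)
    lo <- max(tt[j] - dt, 0); hi <- min(tt[j] + dt, max(t_knots))
    opt <- stats::optimize(function(t) (fx(t) - gold[i, 1])^2 +
                             (fy(t) - gold[i, 2])^2,
                           lower = lo, upper = hi, tol = 1e-10)
    sqrt(min(opt$objective, d2[j]))
  }, numeric(1))
}

#' Success/failure decomposition of segmentation errors
#'
#' Splits per-case errors into a success and a failure distribution by
#' iterative trimming: any case exceeding the mean of the current success
#' set by more than 3 of its standard deviations is moved to the failures,
#' the statistics are recomputed, and the rule is reapplied until the
#' partition is stable.
#'
#' @param errors Numeric vector of per-case errors (>= 2 cases).
#' @return A list with \code{success} and \code{failure} (indices into
#'   \code{errors}), \code{failure_rate} (percent), \code{success_mean} and
#'   \code{success_sd}.
#' @export
split_success_failure <- function(errors) {
  stopifnot(length(errors) >= 2, all(is.finite(errors)))
  success <- seq_along(errors)
  repeat {
    m <- mean(errors[success])
    s <- stats::sd(errors[success])
    if (!is.finite(s)) s <- 0
    keep <- success[errors[success] <= m + 3 * s]
    if (length(keep) == length(success)) break
    if (length(keep) < 2) break  # refuse to trim below 2 cases
    success <- keep
  }
  failure <- setdiff(seq_along(errors), success)
  list(success = success, failure = failure,
       failure_rate = 100 * length(failure) / length(errors),
       success_mean = mean(errors[success]),
       success_sd = if (length(success) > 1) stats::sd(errors[success]) else 0)
}

#' Pixel to millimetre conversion
#'
#' @param px Length in pixels.
#' @param dpi Scanner resolution in dots per inch (> 0); 146 dpi for the
#'   digitized radiographs this package targets, giving about 0.17 mm per
#'   pixel.
#' @return Length in millimetres, \code{px * 25.4 / dpi}.
#' @export
px_to_mm <- function(px, dpi = 146) {
  if (dpi <= 0) stop("dpi must be positive")
  px * 25.4 / dpi
}

#' Per-vertebra segmentation error report
#'
#' Computes, for each vertebra level, the per-case mean point-to-line
#' error, then summarizes: overall mean and median, failure rate under the
#' 3-standard-deviation rule, and mean/SD of the success distribution.
#'
#' @param gold List over cases; each element a named list of gold n x 2
#'   shapes per vertebra.
#' @param fitted Same structure with fitted shapes.
#' @param closed Treat contours as closed loops.
#' @return A data frame with columns \code{vertebra}, \code{mean},
#'   \code{median}, \code{failure_rate}, \code{success_mean},
#'   \code{success_sd}, \code{n_cases}.
#' @export
error_report <- function(gold, fitted, closed = TRUE) {
  stopifnot(length(gold) == length(fitted), length(gold) >= 2)
  levels <- names(gold[[1]])
  rows <- lapply(levels, function(v) {
    errs <- vapply(seq_along(gold), function(i) {
      mean(point_to_line_distance(gold[[i]][[v]], fitted[[i]][[v]],
                                  closed = closed))
    }, numeric(1))
    sp <- split_success_failure(errs)
    data.frame(vertebra = v, mean = mean(errs), median = stats::median(errs),
               failure_rate = sp$failure_rate,
               success_mean = sp$success_mean, success_sd = sp$success_sd,
               n_cases = length(errs))
  })
  do.call(rbind, rows)
}
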