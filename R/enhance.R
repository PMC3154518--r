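#' CLAHE parameters
#'
#' Parameters for contrast-limited adaptive histogram equalization. The image
#' is divided into \code{tiles_x} by \code{tiles_y} contextual regions; each
#' region's histogram is clipped at \code{clip_limit} times the uniform bin
#' height before equalization, which bounds the contrast amplification in
#' homogeneous areas (the dominant failure mode of plain equalization on
#' low-contrast radiographs).
#'
#' @param tiles_x,tiles_y Number of contextual regions horizontally and
#'   vertically (each at least 1).
#' @param clip_limit Relative contrast factor (> 0), expressed as a multiple
#'   of the uniform bin height \code{region_pixel_count / n_bins}. Setting it
#'   to \code{n_bins} (so the absolute limit reaches the region pixel count)
#'   disables clipping and recovers plain regional equalization.
#' @param n_bins Histogram bin count (at least 2).
#' @return An object of class \code{clahe_params}.
#' @export
clahe_params <- function(tiles_x = 8, tiles_y = 8, clip_limit = 2.0,
                         n_bins = 256) {
  stopifnot(tiles_x >= 1, tiles_y >= 1, clip_limit > 0, n_bins >= 2)
  structure(list(tiles_x = as.integer(tiles_x), tiles_y = as.integer(tiles_y),
                 clip_limit = clip_limit, n_bins = as.integer(n_bins)),
            class = "clahe_params")
}

#' Clip a histogram and redistribute the excess
#'
#' Caps every bin at \code{clip_limit_abs} and redistributes the clipped
#' excess uniformly over all bins. Bins pushed above the limit by the
#' redistribution are swept in a single second pass (capped again, remainder
#' redistributed once more), so the final bins may exceed the limit only by
#' the small second-pass residue. The total count is conserved exactly.
#'
#' @param hist Numeric vector of non-negative per-bin counts.
#' @param clip_limit_abs Absolute per-bin cap (>= 1).
#' @return Clipped histogram, same length and same sum as the input.
#' @export
clip_histogram <- function(hist, clip_limit_abs) {
  if (length(hist) == 0L) stop("empty histogram: degenerate region")
  stopifnot(clip_limit_abs >= 1, all(hist >= 0))
  n <- length(hist)
  clipped <- pmin(hist, clip_limit_abs)
  excess <- sum(hist) - sum(clipped)
  clipped <- clipped + excess / n
  # second pass: sweep bins the uniform share pushed back above the limit
  over <- clipped > clip_limit_abs
  residue <- sum(clipped[over] - clip_limit_abs)
  if (residue > 0 && any(!over)) {
    clipped[over] <- clip_limit_abs
    clipped[!over] <- clipped[!over] + residue / sum(!over)
  }
  clipped
}

# Tile geometry: row/col breaks and region centers for a tiles_y x tiles_x grid.
tile_grid <- function(nr, nc, tiles_x, tiles_y) {
  row_breaks <- round(seq(0, nr, length.out = tiles_y + 1))
  col_breaks <- round(seq(0, nc, length.out = tiles_x + 1))
  if (any(diff(row_breaks) < 1) || any(diff(col_breaks) < 1)) {
    stop("tile grid finer than the image: each region needs at least one pixel")
  }
  list(row_breaks = row_breaks, col_breaks = col_breaks,
       row_centers = (head_(row_breaks) + tail_(row_breaks) + 1) / 2,
       col_centers = (head_(col_breaks) + tail_(col_breaks) + 1) / 2)
}
head_ <- function(x) x[-length(x)]
tail_ <- function(x) x[-1]

#' Build per-region equalization transforms
#'
#' Computes, for each contextual region, the clipped-histogram equalization
#' mapping: the region histogram is clipped (\code{\link{clip_histogram}}),
#' its cumulative distribution is scaled to the full output range, and the
#' resulting monotone lookup table maps input level to output level.
#'
#' @param img Numeric intensity matrix in \code{[0, max_level]}.
#' @param params A \code{\link{clahe_params}} object.
#' @param max_level Top of the intensity range (bit-depth dependent).
#' @return An object of class \code{region_transform_grid} holding one lookup
#'   table per region plus the region-center coordinates used for blending.
#' @export
build_region_transforms <- function(img, params = clahe_params(),
                                    max_level = 255) {
  stopifnot(is.matrix(img))
  g <- tile_grid(nrow(img), ncol(img), params$tiles_x, params$tiles_y)
  n_bins <- params$n_bins
  bin_of <- bin_index(img, n_bins, max_level)
  transforms <- matrix(NA_real_, nrow = params$tiles_y * params$tiles_x,
                       ncol = n_bins)
  for (ty in seq_len(params$tiles_y)) {
    rows <- (g$row_breaks[ty] + 1):g$row_breaks[ty + 1]
    for (tx in seq_len(params$tiles_x)) {
      cols <- (g$col_breaks[tx] + 1):g$col_breaks[tx + 1]
      h <- tabulate(bin_of[rows, cols], nbins = n_bins)
      limit <- max(1, params$clip_limit * sum(h) / n_bins)
      ch <- clip_histogram(h, limit)
      transforms[(ty - 1) * params$tiles_x + tx, ] <-
        cumsum(ch) / sum(ch) * max_level
    }
  }
  structure(list(transforms = transforms, grid = g, params = params,
                 max_level = max_level, dim = dim(img)),
            class = "region_transform_grid")
}

bin_index <- function(img, n_bins, max_level) {
  b <- floor(img / (max_level + 1e-9) * n_bins) + 1L
  pmin(pmax(b, 1L), n_bins)
}

#' Apply CLAHE region transforms with bilinear blending
#'
#' Maps every pixel through the four surrounding region-center transforms
#' \eqn{T_A, T_B, T_C, T_D} blended bilinearly:
#' \deqn{s = (1-y)[(1-x) T_A(r) + x T_B(r)] + y[(1-x) T_C(r) + x T_D(r)]}
#' where \eqn{x, y \in [0,1]} are the pixel's horizontal and vertical
#' positions between the centers. In the border band outside the rectangle
#' spanned by region centers the weights clamp to the nearest centers, which
#' degenerates to linear interpolation along edges and to the single nearest
#' transform at the image corners.
#'
#' @param img Intensity matrix with the dimensions the grid was built from.
#' @param grid A \code{\link{build_region_transforms}} result.
#' @return The equalized image, same dimensions, values in
#'   \code{[0, max_level]}.
#' @export
apply_clahe <- function(img, grid) {
  stopifnot(inherits(grid, "region_transform_grid"),
            all(dim(img) == grid$dim))
  p <- grid$params
  g <- grid$grid
  nr <- nrow(img); nc <- ncol(img)
  bins <- bin_index(img, p$n_bins, grid$max_level)

  # per-row vertical tile index and weight (clamped outside the center span)
  iy <- findInterval(seq_len(nr), g$row_centers, all.inside = FALSE)
  iy <- pmin(pmax(iy, 1L), max(1L, p$tiles_y - 1L))
  if (p$tiles_y == 1L) {
    wy <- rep(0, nr)
  } else {
    wy <- (seq_len(nr) - g$row_centers[iy]) /
      (g$row_centers[iy + 1L] - g$row_centers[iy])
    wy <- pmin(pmax(wy, 0), 1)
  }
  ix <- findInterval(seq_len(nc), g$col_centers, all.inside = FALSE)
  ix <- pmin(pmax(ix, 1L), max(1L, p$tiles_x - 1L))
  if (p$tiles_x == 1L) {
    wx <- rep(0, nc)
  } else {
    wx <- (seq_len(nc) - g$col_centers[ix]) /
      (g$col_centers[ix + 1L] - g$col_centers[ix])
    wx <- pmin(pmax(wx, 0), 1)
  }

  ty_top <- matrix(iy, nr, nc)                 # vertical tile above
  tx_left <- matrix(ix, nr, nc, byrow = TRUE)  # horizontal tile to the left
  x <- matrix(wx, nr, nc, byrow = TRUE)
  y <- matrix(wy, nr, nc)
  tx_right <- pmin(tx_left + ifelse(p$tiles_x == 1L, 0L, 1L), p$tiles_x)
  ty_bot <- pmin(ty_top + ifelse(p$tiles_y == 1L, 0L, 1L), p$tiles_y)

  region_id <- function(ty, tx) (ty - 1L) * p$tiles_x + tx
  lut <- function(reg) grid$transforms[cbind(as.vector(reg), as.vector(bins))]
  ta <- lut(region_id(ty_top, tx_left))
  tb <- lut(region_id(ty_top, tx_right))
  tc <- lut(region_id(ty_bot, tx_left))
  td <- lut(region_id(ty_bot, tx_right))
  s <- (1 - y) * ((1 - x) * ta + x * tb) + y * ((1 - x) * tc + x * td)
  matrix(s, nr, nc)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Convenience wrapper: builds the regional transforms and applies them with
#' bilinear blending.
#'
#' @inheritParams build_region_transforms
#' @return The equalized image.
#' @export
clahe <- function(img, params = clahe_params(), max_level = 255) {
  apply_clahe(img, build_region_transforms(img, params, max_level))
}
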