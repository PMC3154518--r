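#' Spine-curvature model
#'
#' An ordered landmark sequence describing the anterior corners of the
#' cervical vertebral bodies, top to bottom: by default 10 landmarks (the
#' upper and lower anterior corner of each of C3-C7). The model is used
#' only to locate corners along the spine, not to describe the curvature
#' precisely.
#'
#' @param mean_shape n x 2 landmark matrix, ordered top to bottom.
#' @return An object of class \code{curvature_model}.
#' @export
curvature_model <- function(mean_shape) {
  stopifnot(is.matrix(mean_shape), nrow(mean_shape) >= 2)
  n <- nrow(mean_shape)
  axis <- mean_shape[n, ] - mean_shape[1, ]
  proj <- as.vector((mean_shape - matrix(mean_shape[1, ], n, 2,
                                         byrow = TRUE)) %*% axis)
  if (any(diff(proj) <= 0)) {
    stop("curvature-model landmarks must be strictly ordered along the axis")
  }
  structure(list(mean_shape = mean_shape, n_landmarks = n),
            class = "curvature_model")
}

#' Build a spine-curvature model from training sequences
#'
#' Procrustes-aligns the training landmark sequences and takes their mean.
#'
#' @param samples List (>= 2) of equally sized n x 2 landmark matrices,
#'   each ordered top to bottom.
#' @return A \code{\link{curvature_model}}.
#' @export
build_curvature_model <- function(samples) {
  stopifnot(length(samples) >= 2)
  ns <- vapply(samples, nrow, 1L)
  if (length(unique(ns)) != 1) {
    stop("curvature samples have inconsistent landmark counts: ",
         paste(unique(ns), collapse = ", "))
  }
  al <- procrustes_align_set(samples)
  curvature_model(al$mean)
}

#' Region-of-interest clicks
#'
#' The two user-supplied points anchoring the spine-curvature model: the
#' upper anterior corner of C3 and the lower anterior corner of C7.
#'
#' @param top,bottom Length-2 pixel coordinates \code{c(x, y)}.
#' @return An object of class \code{roi_clicks}.
#' @export
roi_clicks <- function(top, bottom) {
  stopifnot(length(top) == 2, length(bottom) == 2)
  if (all(top == bottom)) stop("ROI clicks must be two distinct points")
  structure(list(top = as.numeric(top), bottom = as.numeric(bottom)),
            class = "roi_clicks")
}

#' Align the curvature model to the ROI clicks
#'
#' Applies the unique orientation-preserving similarity transform that maps
#' the model's first landmark exactly onto \code{clicks$top} and its last
#' landmark exactly onto \code{clicks$bottom}; interior landmarks follow,
#' preserving the model's relative geometry.
#'
#' @param model A \code{\link{curvature_model}}.
#' @param clicks A \code{\link{roi_clicks}} object.
#' @return Positioned n x 2 landmark matrix.
#' @export
align_model_to_roi <- function(model, clicks) {
  stopifnot(inherits(model, "curvature_model"), inherits(clicks, "roi_clicks"))
  z <- as_complex_shape(model$mean_shape)
  n <- length(z)
  zt <- complex(real = clicks$top[1], imaginary = clicks$top[2])
  zb <- complex(real = clicks$bottom[1], imaginary = clicks$bottom[2])
  a <- (zb - zt) / (z[n] - z[1])
  w <- a * (z - z[1]) + zt
  cbind(x = Re(w), y = Im(w))
}

#' Match detected corners to positioned curvature landmarks
#'
#' Walks the positioned landmarks strictly top to bottom (in the order the
#' model defines) and assigns each the nearest detected corner, restricted
#' to corners whose projection onto the click axis lies strictly below the
#' previously matched one — the ordering constraint that prevents the upper
#' and lower corners of successive vertebrae from swapping. Landmarks with
#' no corner within \code{max_radius} are flagged unmatched and fall back
#' to their model-predicted position.
#'
#' @param positioned n x 2 matrix from \code{\link{align_model_to_roi}}.
#' @param corners A \code{\link{detect_corners}} result (or any data frame
#'   with \code{x}, \code{y}).
#' @param clicks The \code{\link{roi_clicks}} defining the top-to-bottom
#'   axis.
#' @param max_radius Maximum landmark-to-corner assignment distance;
#'   default a quarter of the inter-click distance divided by the landmark
#'   count.
#' @param labels Vertebra labels, recycled two landmarks per vertebra.
#' @return An object of class \code{vertebra_anchors}: data frame with
#'   \code{landmark}, \code{vertebra}, \code{role} ("upper"/"lower"),
#'   \code{x}, \code{y}, \code{matched}.
#' @export
match_corners <- function(positioned, corners, clicks, max_radius = NULL,
                          labels = paste0("C", 3:7)) {
  stopifnot(inherits(clicks, "roi_clicks"))
  if (nrow(corners) == 0) stop("empty corner set")
  n <- nrow(positioned)
  axis <- clicks$bottom - clicks$top
  d_clicks <- sqrt(sum(axis^2))
  u <- axis / d_clicks
  if (is.null(max_radius)) max_radius <- 0.25 * d_clicks / n
  proj <- (corners$x - clicks$top[1]) * u[1] + (corners$y - clicks$top[2]) * u[2]
  out_x <- numeric(n); out_y <- numeric(n); matched <- logical(n)
  last_proj <- -Inf
  for (i in seq_len(n)) {
    d <- sqrt((corners$x - positioned[i, 1])^2 +
                (corners$y - positioned[i, 2])^2)
    ok <- d <= max_radius & proj > last_proj
    if (any(ok)) {
      j <- which(ok)[which.min(d[ok])]
      out_x[i] <- corners$x[j]; out_y[i] <- corners$y[j]
      matched[i] <- TRUE
      last_proj <- proj[j]
    } else {
      out_x[i] <- positioned[i, 1]; out_y[i] <- positioned[i, 2]
      p <- (out_x[i] - clicks$top[1]) * u[1] + (out_y[i] - clicks$top[2]) * u[2]
      last_proj <- max(last_proj, p)
    }
  }
  vert <- rep(labels, each = 2, length.out = n)
  role <- rep(c("upper", "lower"), length.out = n)
  structure(data.frame(landmark = seq_len(n), vertebra = vert, role = role,
                       x = out_x, y = out_y, matched = matched),
            class = c("vertebra_anchors", "data.frame"))
}

#' Initialize per-vertebra shapes from matched anchors
#'
#' For each vertebra, similarity-fits the mean vertebra shape to the
#' vertebra's two matched anterior corners with the same exact two-point
#' transform used for the curvature model, giving the starting shape for
#' the local Active Shape Model search.
#'
#' @param anchors A \code{\link{match_corners}} result.
#' @param model The per-vertebra \code{shape_model}.
#' @param anchor_indices Indices (length 2) of the upper- and
#'   lower-anterior-corner landmarks within the vertebra shape.
#' @return Named list (one per vertebra) of n x 2 initial shapes.
#' @export
init_vertebra_shapes <- function(anchors, model, anchor_indices = c(1, 10)) {
  stopifnot(inherits(model, "shape_model"), length(anchor_indices) == 2)
  mean_mat <- shape_from_vector(model$mean_shape)
  z <- as_complex_shape(mean_mat)
  za <- z[anchor_indices[1]]; zb <- z[anchor_indices[2]]
  out <- list()
  for (v in unique(anchors$vertebra)) {
    rows <- anchors[anchors$vertebra == v, ]
    up <- rows[rows$role == "upper", ]; lo <- rows[rows$role == "lower", ]
    zt <- complex(real = up$x[1], imaginary = up$y[1])
    zl <- complex(real = lo$x[1], imaginary = lo$y[1])
    a <- (zl - zt) / (zb - za)
    w <- a * (z - za) + zt
    out[[v]] <- cbind(x = Re(w), y = Im(w))
  }
  out
}
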