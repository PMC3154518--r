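#' Synthetic radiograph specification
#'
#' Describes a radiograph-like test image: \code{n_vertebrae} brighter
#' rounded quadrilateral vertebral bodies stacked along a curved spine
#' axis on a darker background, with blurred ("blended") boundaries, a
#' smooth illumination ramp and additive Gaussian noise — emulating the
#' low-contrast cervical radiographs the pipeline targets, at desk scale
#' (512 px; the full clinical scale of about 1763 x 1755 px is available
#' through \code{image_size}).
#'
#' @param image_size Square image side in pixels.
#' @param n_vertebrae Number of vertebral bodies (default 5: C3-C7).
#' @param curvature Lateral bow amplitude of the spine axis, pixels.
#' @param vertebra_width,vertebra_height Body size in pixels.
#' @param gap Inter-body spacing in pixels.
#' @param intensity_contrast Body-over-background intensity difference
#'   (0-255 scale).
#' @param background Background intensity level.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param illumination_gradient Amplitude of the smooth diagonal
#'   illumination ramp.
#' @param corner_radius Corner rounding radius in pixels (0 disables;
#'   rounded corners stress the corner detector realistically).
#' @param blur_sigma Gaussian blur applied to the rendered scene.
#' @param seed RNG seed; rendering is bit-reproducible per seed.
#' @return An object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(image_size = 512, n_vertebrae = 5, curvature = 30,
                           vertebra_width = 70, vertebra_height = 50,
                           gap = 18, intensity_contrast = 60,
                           background = 90, noise_sd = 4,
                           illumination_gradient = 20, corner_radius = 2,
                           blur_sigma = 1.5, seed = 1) {
  stopifnot(image_size > 0, n_vertebrae >= 1, vertebra_width > 0,
            vertebra_height > 0, gap >= 0, noise_sd >= 0, corner_radius >= 0)
  total <- n_vertebrae * vertebra_height + (n_vertebrae - 1) * gap
  if (total + 2 * vertebra_width > image_size) {
    stop("vertebral column (", total, " px plus margins) does not fit in a ",
         image_size, " px image")
  }
  structure(as.list(environment())[c(
    "image_size", "n_vertebrae", "curvature", "vertebra_width",
    "vertebra_height", "gap", "intensity_contrast", "background",
    "noise_sd", "illumination_gradient", "corner_radius", "blur_sigma",
    "seed")], class = "synthetic_spec")
}

# vertebra quadrilateral corners for one spec; returns per-vertebra list of
# 4 x 2 corner matrices in the order upper-anterior, upper-posterior,
# lower-posterior, lower-anterior (anterior = left)
vertebra_geometry <- function(spec) {
  n <- spec$n_vertebrae
  total <- n * spec$vertebra_height + (n - 1) * spec$gap
  y0 <- (spec$image_size - total) / 2
  y1 <- y0 + total
  cx <- spec$image_size / 2
  bow <- function(y) {
    t <- (y - y0) / (y1 - y0)
    cx + spec$curvature * 4 * t * (1 - t) - spec$curvature
  }
  dbow <- function(y) {
    t <- (y - y0) / (y1 - y0)
    spec$curvature * 4 * (1 - 2 * t) / (y1 - y0)
  }
  lapply(seq_len(n), function(i) {
    yc <- y0 + spec$vertebra_height / 2 +
      (i - 1) * (spec$vertebra_height + spec$gap)
    center <- c(bow(yc), yc)
    tangent <- c(dbow(yc), 1)
    tangent <- tangent / sqrt(sum(tangent^2))
    normal <- c(-tangent[2], tangent[1])  # anterior (left) side
    h2 <- spec$vertebra_height / 2; w2 <- spec$vertebra_width / 2
    rbind(ua = center - h2 * tangent + w2 * normal,
          up = center - h2 * tangent - w2 * normal,
          lp = center + h2 * tangent - w2 * normal,
          la = center + h2 * tangent + w2 * normal)
  })
}

# inset a convex polygon (rows = CCW or CW consistent vertices) by r:
# every edge moved toward the interior, vertices re-intersected
inset_convex_polygon <- function(poly, r) {
  if (r <= 0) return(poly)
  m <- nrow(poly)
  cen <- colMeans(poly)
  lines <- lapply(seq_len(m), function(i) {
    a <- poly[i, ]; b <- poly[if (i == m) 1 else i + 1, ]
    d <- b - a; d <- d / sqrt(sum(d^2))
    nrm <- c(-d[2], d[1])
    if (sum((cen - a) * nrm) < 0) nrm <- -nrm  # point inward
    list(p = a + r * nrm, d = d)
  })
  out <- matrix(NA_real_, m, 2)
  for (i in seq_len(m)) {
    l1 <- lines[[if (i == 1) m else i - 1]]; l2 <- lines[[i]]
    # intersect p1 + s d1 = p2 + u d2
    A <- cbind(l1$d, -l2$d)
    s <- solve(A, l2$p - l1$p)[1]
    out[i, ] <- l1$p + s * l1$d
  }
  out
}

# boolean mask of a convex quadrilateral with rounded corners
render_quad_mask <- function(nr, nc, poly, corner_radius) {
  inner <- inset_convex_polygon(poly, corner_radius)
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  cs <- max(1, floor(xr[1] - 2)):min(nc, ceiling(xr[2] + 2))
  rs <- max(1, floor(yr[1] - 2)):min(nr, ceiling(yr[2] + 2))
  px <- rep(cs, each = length(rs))
  py <- rep(rs, times = length(cs))
  m <- nrow(inner)
  inside <- rep(TRUE, length(px))
  mind <- rep(Inf, length(px))
  for (i in seq_len(m)) {
    a <- inner[i, ]; b <- inner[if (i == m) 1 else i + 1, ]
    d <- b - a
    cr <- (px - a[1]) * d[2] - (py - a[2]) * d[1]
    inside <- inside & (cr * sign(polygon_orientation(inner)) <= 0)
    mind <- pmin(mind, dist_to_segment(cbind(px, py), a, b))
  }
  sel <- inside | mind <= corner_radius
  mask <- matrix(FALSE, nr, nc)
  mask[cbind(py[sel], px[sel])] <- TRUE
  mask
}

polygon_orientation <- function(poly) {
  m <- nrow(poly)
  nxt <- poly[c(2:m, 1), , drop = FALSE]
  sign(sum(poly[, 1] * nxt[, 2] - nxt[, 1] * poly[, 2]))
}

# evenly spaced samples along a polygon boundary (closed), about `spacing`
# px apart, starting at the first vertex
sample_polygon_boundary <- function(poly, spacing = 1) {
  m <- nrow(poly)
  pts <- rbind(poly, poly[1, ])
  out <- list()
  for (i in seq_len(m)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1, ceiling(len / spacing))
    t <- (seq_len(k) - 1) / k
    out[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  pts <- do.call(rbind, out)
  colnames(pts) <- c("x", "y")
  pts
}

# n_per_edge evenly spaced landmarks per edge (corner + interior points):
# with n_per_edge = 3 this gives 12 landmarks, corners at 1, 4, 7, 10
polygon_landmarks <- function(poly, n_per_edge = 3) {
  m <- nrow(poly)
  pts <- rbind(poly, poly[1, ])
  out <- list()
  for (i in seq_len(m)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    t <- (seq_len(n_per_edge) - 1) / n_per_edge
    out[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  lm <- do.call(rbind, out)
  colnames(lm) <- c("x", "y")
  lm
}

#' Render a synthetic radiograph with ground truth
#'
#' Renders the scene a \code{\link{synthetic_spec}} describes and returns
#' the image together with exact ground truth: per-vertebra corner
#' coordinates (of the underlying sharp quadrilaterals), dense boundary
#' contours, the 10-landmark anterior-corner sequence in curvature-model
#' order, and 12-landmark per-vertebra shapes for segmentation (corners at
#' landmark indices 1, 4, 7, 10; anterior corners at 1 and 10).
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @return A list with \code{image} (intensity matrix, 0-255) and
#'   \code{truth}, itself a list: \code{corners}, \code{boundaries},
#'   \code{anterior_landmarks}, \code{shapes}, \code{clicks} (the ideal
#'   ROI clicks) and \code{spec}.
#' @export
render_radiograph <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  nr <- nc <- spec$image_size
  quads <- vertebra_geometry(spec)
  xn <- matrix(seq_len(nc) / nc, nr, nc, byrow = TRUE)
  yn <- matrix(seq_len(nr) / nr, nr, nc)
  img <- spec$background +
    spec$illumination_gradient * ((xn + yn) / 2 - 0.5)
  for (q in quads) {
    mask <- render_quad_mask(nr, nc, q, spec$corner_radius)
    img[mask] <- img[mask] + spec$intensity_contrast
  }
  if (spec$blur_sigma > 0) img <- gaussian_smooth(img, spec$blur_sigma)
  if (spec$noise_sd > 0) {
    img <- img + with_seed(spec$seed,
                           matrix(stats::rnorm(nr * nc, 0, spec$noise_sd),
                                  nr, nc))
  }
  img <- pmin(pmax(img, 0), 255)
  anterior <- do.call(rbind, lapply(quads, function(q) q[c("ua", "la"), ]))
  colnames(anterior) <- c("x", "y")
  truth <- list(
    corners = quads,
    boundaries = lapply(quads, sample_polygon_boundary),
    anterior_landmarks = anterior,
    shapes = stats::setNames(lapply(quads, polygon_landmarks),
                             paste0("C", seq(3, 2 + spec$n_vertebrae))),
    clicks = roi_clicks(quads[[1]]["ua", ],
                        quads[[length(quads)]]["la", ]),
    spec = spec
  )
  list(image = img, truth = truth)
}

#' Sample training shapes from a shape model
#'
#' Draws \code{n} shapes \code{mean + modes b} with independent zero-mean
#' Gaussian coefficients of standard deviation
#' \code{coeff_sd_scale * sqrt(variance)} per mode, each under a random
#' similarity pose (rotation within \code{rotation_range} radians, scale
#' within \code{scale_range}, translation within
#' \code{translation_range} px). Deterministic per seed.
#'
#' By default (\code{standardize = TRUE}, and when \code{n >= 3}) the drawn
#' coefficients of each mode are centred and rescaled to have exactly the
#' target sample standard deviation, so the generated set carries the
#' model's variances as exact ground truth: parameter-recovery experiments
#' then measure the error of the alignment and decomposition machinery
#' rather than the sampling noise of a finite Gaussian draw.
#'
#' @param model A \code{shape_model}.
#' @param n Number of shapes.
#' @param coeff_sd_scale Multiplier on the per-mode standard deviation.
#' @param seed RNG seed.
#' @param rotation_range,scale_range,translation_range Pose jitter bounds.
#' @param standardize Rescale coefficients to the exact target SD per mode.
#' @return List of n x 2 shapes.
#' @export
sample_training_shapes <- function(model, n, coeff_sd_scale = 1, seed = 1,
                                   rotation_range = c(-0.2, 0.2),
                                   scale_range = c(0.9, 1.1),
                                   translation_range = c(-10, 10),
                                   standardize = TRUE) {
  stopifnot(inherits(model, "shape_model"), n >= 1)
  with_seed(seed, {
    B <- matrix(0, n, model$t)
    if (model$t > 0) {
      target_sd <- coeff_sd_scale * sqrt(model$variances)
      for (j in seq_len(model$t)) {
        bj <- stats::rnorm(n, 0, target_sd[j])
        if (standardize && n >= 3 && stats::sd(bj) > 0) {
          bj <- (bj - mean(bj)) / stats::sd(bj) * target_sd[j]
        }
        B[, j] <- bj
      }
    }
    lapply(seq_len(n), function(i) {
      pose <- pose_params(
        scale = stats::runif(1, scale_range[1], scale_range[2]),
        rotation = stats::runif(1, rotation_range[1], rotation_range[2]),
        translation = stats::runif(2, translation_range[1],
                                   translation_range[2]))
      generate_shape(model, B[i, ], pose)
    })
  })
}

#' Synthetic vertebra training shapes
#'
#' 12-landmark quadrilateral vertebra shapes with independent Gaussian
#' jitter on the four corners (landmarks re-derived from the jittered
#' corners), for training shape models without clinical data.
#'
#' @param n Number of shapes.
#' @param width,height Nominal body size in pixels.
#' @param jitter_sd Corner jitter standard deviation in pixels.
#' @param seed RNG seed.
#' @return List of 12 x 2 shapes.
#' @export
synthetic_vertebra_shapes <- function(n, width = 70, height = 50,
                                      jitter_sd = 2.5, seed = 1) {
  # corner order ua, up, lp, la (anterior = left)
  base <- rbind(c(-width / 2, -height / 2), c(width / 2, -height / 2),
                c(width / 2, height / 2), c(-width / 2, height / 2))
  with_seed(seed, lapply(seq_len(n), function(i) {
    q <- base + matrix(stats::rnorm(8, 0, jitter_sd), 4, 2)
    polygon_landmarks(q)
  }))
}

#' Known two-mode reference shape model
#'
#' A 12-landmark vertebra shape model with exactly two modes of known
#' variance, for parameter-recovery experiments. The mean is the
#' normalized quadrilateral vertebra shape; the modes are random unit
#' vectors orthogonalized against the 4-dimensional similarity subspace
#' (translations, scaling, rotation of the mean) and against each other,
#' so Procrustes alignment cannot absorb them.
#'
#' @param variances Length-2 descending mode variances (squared units of
#'   the unit-size mean shape).
#' @param seed RNG seed for the mode directions.
#' @return A \code{shape_model} with \code{t = 2}.
#' @export
synthetic_two_mode_model <- function(variances = c(4e-4, 1e-4), seed = 5) {
  stopifnot(length(variances) == 2, diff(variances) <= 0)
  mean_mat <- polygon_landmarks(rbind(c(-35, -25), c(35, -25),
                                      c(35, 25), c(-35, 25)))
  z <- as_complex_shape(mean_mat)
  z <- z - mean(z)
  z <- z / sqrt(sum(Mod(z)^2))
  mean_v <- c(Re(z), Im(z))
  n <- length(z)
  sim <- cbind(c(rep(1, n), rep(0, n)), c(rep(0, n), rep(1, n)),
               mean_v, c(-Im(z), Re(z)))
  modes <- with_seed(seed, {
    M <- cbind(sim, matrix(stats::rnorm(4 * n), 2 * n, 2))
    qr.Q(qr(M))[, 5:6, drop = FALSE]
  })
  structure(list(mean_shape = mean_v, modes = modes,
                 variances = as.numeric(variances), t = 2L,
                 n_landmarks = n),
            class = "shape_model")
}

#' Synthetic spine-curvature training sequences
#'
#' Anterior-corner landmark sequences (upper and lower anterior corner per
#' vertebra, top to bottom) computed analytically from randomized scene
#' geometries, for training the spine-curvature model.
#'
#' @param n Number of sequences.
#' @param seed RNG seed.
#' @return List of 10 x 2 landmark matrices.
#' @export
synthetic_curvature_samples <- function(n, seed = 1) {
  with_seed(seed, lapply(seq_len(n), function(i) {
    spec <- synthetic_spec(
      curvature = stats::rnorm(1, 30, 8),
      vertebra_height = stats::runif(1, 44, 56),
      vertebra_width = stats::runif(1, 62, 78),
      gap = stats::runif(1, 14, 22),
      noise_sd = 0)
    quads <- vertebra_geometry(spec)
    ant <- do.call(rbind, lapply(quads, function(q) q[c("ua", "la"), ]))
    colnames(ant) <- c("x", "y")
    ant
  }))
}
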