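#' Pose parameters of a similarity transform
#'
#' @param scale Positive scale factor.
#' @param rotation Rotation in radians (counter-clockwise in x-right,
#'   y-down image coordinates this is a clockwise screen rotation; the
#'   convention is internal and consistent).
#' @param translation Length-2 offset \code{c(tx, ty)}.
#' @return An object of class \code{pose_params}.
#' @export
pose_params <- function(scale = 1, rotation = 0, translation = c(0, 0)) {
  stopifnot(scale > 0, length(translation) == 2)
  structure(list(scale = scale, rotation = rotation,
                 translation = translation),
            class = "pose_params")
}

#' Apply a pose to a shape
#'
#' @param shape n x 2 landmark matrix.
#' @param pose A \code{\link{pose_params}} object.
#' @return Transformed n x 2 matrix.
#' @export
apply_pose <- function(shape, pose) {
  z <- complex(real = shape[, 1], imaginary = shape[, 2])
  a <- pose$scale * exp(1i * pose$rotation)
  w <- a * z + complex(real = pose$translation[1],
                       imaginary = pose$translation[2])
  cbind(x = Re(w), y = Im(w))
}

invert_pose <- function(pose) {
  a <- pose$scale * exp(1i * pose$rotation)
  t <- complex(real = pose$translation[1], imaginary = pose$translation[2])
  ai <- 1 / a
  ti <- -t / a
  pose_params(Mod(ai), Arg(ai), c(Re(ti), Im(ti)))
}

as_complex_shape <- function(shape) {
  complex(real = shape[, 1], imaginary = shape[, 2])
}

#' Procrustes alignment of one shape onto another
#'
#' Finds the similarity transform (scale, rotation, translation) minimizing
#' the sum of squared distances between corresponding landmarks of
#' \code{moving} and \code{fixed}; the closed-form least-squares solution in
#' complex coordinates.
#'
#' @param moving,fixed n x 2 landmark matrices with equal n.
#' @return A list with \code{pose} (mapping \code{moving} onto
#'   \code{fixed}), \code{aligned} (the transformed moving shape) and
#'   \code{residual} (the minimized sum of squares).
#' @export
procrustes_pair <- function(moving, fixed) {
  stopifnot(nrow(moving) == nrow(fixed))
  zm <- as_complex_shape(moving); zf <- as_complex_shape(fixed)
  cm <- mean(zm); cf <- mean(zf)
  zm0 <- zm - cm; zf0 <- zf - cf
  denom <- sum(Mod(zm0)^2)
  if (denom < .Machine$double.eps) {
    stop("degenerate shape: all landmarks coincide")
  }
  a <- sum(Conj(zm0) * zf0) / denom
  t <- cf - a * cm
  aligned <- a * zm + t
  pose <- pose_params(Mod(a), Arg(a), c(Re(t), Im(t)))
  list(pose = pose,
       aligned = cbind(x = Re(aligned), y = Im(aligned)),
       residual = sum(Mod(aligned - zf)^2))
}

# gauge-fixing normalization: centroid at origin, unit centroid size,
# first-to-last landmark axis at the reference angle
normalize_shape <- function(shape, ref_angle) {
  z <- as_complex_shape(shape)
  z <- z - mean(z)
  size <- sqrt(sum(Mod(z)^2))
  if (size < .Machine$double.eps) stop("degenerate shape: zero size")
  z <- z / size
  ax <- z[length(z)] - z[1]
  if (Mod(ax) > .Machine$double.eps) {
    z <- z * exp(1i * (ref_angle - Arg(ax)))
  }
  cbind(x = Re(z), y = Im(z))
}

#' Generalized Procrustes alignment of a shape set
#'
#' Iteratively aligns every shape to the evolving mean, re-estimates and
#' normalizes the mean (centred, unit centroid size, first-to-last landmark
#' axis at a fixed reference angle to remove the similarity gauge freedom),
#' and stops when the mean moves less than \code{tol} RMS between
#' iterations.
#'
#' @param shapes List of n x 2 landmark matrices (>= 2, equal n).
#' @param tol Convergence threshold on mean-shape RMS movement.
#' @param max_iter Iteration cap.
#' @return A list with \code{aligned} (list of shapes), \code{mean} (the
#'   normalized mean shape) and \code{iterations}.
#' @export
procrustes_align_set <- function(shapes, tol = 1e-8, max_iter = 100) {
  stopifnot(length(shapes) >= 2)
  n <- nrow(shapes[[1]])
  if (!all(vapply(shapes, nrow, 1L) == n)) {
    stop("all shapes must have the same landmark count")
  }
  z1 <- as_complex_shape(shapes[[1]])
  ref_angle <- Arg(z1[n] - z1[1])
  mean_shape <- normalize_shape(shapes[[1]], ref_angle)
  for (it in seq_len(max_iter)) {
    aligned <- lapply(shapes, function(s) procrustes_pair(s, mean_shape)$aligned)
    new_mean <- Reduce(`+`, aligned) / length(aligned)
    new_mean <- normalize_shape(new_mean, ref_angle)
    delta <- sqrt(mean((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) {
      aligned <- lapply(shapes, function(s) procrustes_pair(s, mean_shape)$aligned)
      return(list(aligned = aligned, mean = mean_shape, iterations = it))
    }
  }
  stop("Procrustes alignment did not converge in ", max_iter,
       " iterations (last mean movement ", format(delta), ")")
}

#' Build a PCA shape model
#'
#' Eigendecomposition of the landmark covariance of aligned shapes. The
#' retained mode count \code{t} is the smallest number of modes explaining
#' at least \code{variance_fraction} of the total variance. A generated
#' shape is \code{mean + modes \%*\% b}.
#'
#' @param aligned List of aligned n x 2 shapes (>= 2).
#' @param variance_fraction Proportion of variance to retain, in (0, 1].
#' @return An object of class \code{shape_model}: \code{mean_shape}
#'   (2n-vector, x-block then y-block), \code{modes} (2n x t orthonormal
#'   matrix), \code{variances} (descending eigenvalues), \code{t} and
#'   \code{n_landmarks}.
#' @export
build_pca_model <- function(aligned, variance_fraction = 0.95) {
  stopifnot(length(aligned) >= 2)
  if (variance_fraction <= 0 || variance_fraction > 1) {
    stop("variance_fraction must be in (0, 1]")
  }
  X <- do.call(rbind, lapply(aligned, as.vector))
  xbar <- colMeans(X)
  S <- stats::cov(X)
  eg <- eigen(S, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  total <- sum(vals)
  if (total < .Machine$double.eps) {
    t_keep <- 0L
  } else {
    t_keep <- which(cumsum(vals) / total >= variance_fraction - 1e-12)[1]
  }
  structure(list(mean_shape = xbar,
                 modes = eg$vectors[, seq_len(t_keep), drop = FALSE],
                 variances = vals[seq_len(t_keep)],
                 t = t_keep,
                 n_landmarks = ncol(X) / 2),
            class = "shape_model")
}

#' Reassemble a landmark matrix from a 2n shape vector
#'
#' @param v Numeric vector of length 2n: the x block followed by the y
#'   block, the layout \code{shape_model} objects use.
#' @return n x 2 landmark matrix.
#' @export
shape_from_vector <- function(v) {
  n <- length(v) / 2
  cbind(x = v[seq_len(n)], y = v[n + seq_len(n)])
}

#' Generate a shape from model coefficients
#'
#' @param model A \code{\link{build_pca_model}} result.
#' @param b Mode coefficients, length \code{model$t}.
#' @param pose Optional \code{\link{pose_params}} applied after generation.
#' @return n x 2 landmark matrix \code{pose(mean + modes b)}.
#' @export
generate_shape <- function(model, b = numeric(model$t),
                           pose = pose_params()) {
  stopifnot(inherits(model, "shape_model"))
  if (length(b) != model$t) {
    stop("coefficient vector length ", length(b),
         " does not match mode count ", model$t)
  }
  v <- model$mean_shape
  if (model$t > 0) v <- v + as.vector(model$modes %*% b)
  apply_pose(shape_from_vector(v), pose)
}

#' Project a shape onto a model
#'
#' Recovers the pose (Procrustes alignment of the model mean onto the
#' shape) and the mode coefficients \code{b = t(P) (pose^-1(shape) - mean)},
#' clamped to plus or minus 3 standard deviations per mode so the projected
#' shape stays in the model's allowable region.
#'
#' @param model A \code{shape_model}.
#' @param shape n x 2 landmark matrix.
#' @param b_limit Clamp in units of \code{sqrt(variance)} per mode.
#' @return A list with \code{b} (clamped coefficients) and \code{pose}.
#' @export
project_shape <- function(model, shape, b_limit = 3) {
  stopifnot(inherits(model, "shape_model"),
            nrow(shape) == model$n_landmarks)
  mean_mat <- shape_from_vector(model$mean_shape)
  pose <- procrustes_pair(mean_mat, shape)$pose
  local <- apply_pose(shape, invert_pose(pose))
  if (model$t == 0) {
    return(list(b = numeric(0), pose = pose))
  }
  b <- as.vector(t(model$modes) %*% (as.vector(local) - model$mean_shape))
  lim <- b_limit * sqrt(model$variances)
  list(b = pmin(pmax(b, -lim), lim), pose = pose)
}

#' Read landmark shapes from CSV
#'
#' Expects columns \code{shape_id}, \code{landmark_index}, \code{x},
#' \code{y}; returns a list of n x 2 matrices ordered by
#' \code{landmark_index} within each \code{shape_id}.
#'
#' @param path CSV file path.
#' @return Named list of shapes.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path)
  need <- c("shape_id", "landmark_index", "x", "y")
  if (!all(need %in% names(df))) {
    stop("landmark CSV must have columns: ", paste(need, collapse = ", "))
  }
  lapply(split(df, df$shape_id), function(d) {
    d <- d[order(d$landmark_index), ]
    cbind(x = d$x, y = d$y)
  })
}

#' Write landmark shapes to CSV
#'
#' @param shapes List of n x 2 matrices.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_landmarks <- function(shapes, path) {
  ids <- names(shapes)
  if (is.null(ids)) ids <- as.character(seq_along(shapes))
  df <- do.call(rbind, lapply(seq_along(shapes), function(i) {
    s <- shapes[[i]]
    data.frame(shape_id = ids[i], landmark_index = seq_len(nrow(s)),
               x = s[, 1], y = s[, 2])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a shape model to JSON
#'
#' @param model A \code{shape_model}.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_shape_model <- function(model, path) {
  stopifnot(inherits(model, "shape_model"))
  obj <- list(mean_shape = model$mean_shape,
              modes = model$modes,
              variances = model$variances,
              t = model$t,
              n_landmarks = model$n_landmarks)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a shape model from JSON
#'
#' @param path JSON file written by \code{\link{write_shape_model}}.
#' @return A \code{shape_model}.
#' @export
read_shape_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  modes <- obj$modes
  if (is.null(modes) || length(modes) == 0) {
    modes <- matrix(0, length(obj$mean_shape), 0)
  }
  if (!is.matrix(modes)) modes <- matrix(modes, ncol = max(1, obj$t))
  structure(list(mean_shape = as.numeric(obj$mean_shape),
                 modes = modes,
                 variances = as.numeric(obj$variances),
                 t = as.integer(obj$t),
                 n_landmarks = as.integer(obj$n_landmarks)),
            class = "shape_model")
}
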