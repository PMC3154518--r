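# bilinear interpolation at (x, y) positions, coordinates clamped to the
# image (edge padding)
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 1), nc)
  y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1); y0 <- pmin(floor(y), nr - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(y0, x0)]
  i01 <- img[cbind(y0, x0 + 1)]
  i10 <- img[cbind(y0 + 1, x0)]
  i11 <- img[cbind(y0 + 1, x0 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

# gradient-intensity samples along a unit direction: magnitude of the
# directional derivative of intensity, central differences at unit steps
# t = offsets along the normal (vector), centered on `point`
profile_gradient <- function(img, point, normal, t) {
  lo <- bilinear_sample(img, point[1] + (t - 1) * normal[1],
                        point[2] + (t - 1) * normal[2])
  hi <- bilinear_sample(img, point[1] + (t + 1) * normal[1],
                        point[2] + (t + 1) * normal[2])
  abs((hi - lo) / 2)
}

normalize_profile <- function(g) {
  s <- sum(abs(g))
  if (s > 0) g / s else g
}

#' Sample a grey-level gradient profile at a landmark
#'
#' Samples the magnitude of the directional derivative of image intensity at
#' \code{2k + 1} unit steps along the landmark normal, centred on the
#' landmark, and normalizes the profile by its sum of absolute values.
#' Samples falling outside the image are clamped to the border (edge
#' padding).
#'
#' @param img Intensity matrix.
#' @param point Length-2 landmark position \code{c(x, y)}.
#' @param normal Length-2 direction; need not be unit length, must be
#'   nonzero.
#' @param k Profile half-length; the profile has \code{2k + 1} samples.
#' @return Numeric vector of length \code{2k + 1}.
#' @export
sample_profile <- function(img, point, normal, k = 6) {
  nn <- sqrt(sum(normal^2))
  if (nn == 0) stop("zero-length profile normal")
  normal <- normal / nn
  normalize_profile(profile_gradient(img, point, normal, -k:k))
}

#' Landmark normals of a shape
#'
#' The normal at each landmark is perpendicular to the chord joining its
#' neighbouring landmarks, with the shape treated as closed.
#'
#' @param shape n x 2 landmark matrix.
#' @return n x 2 matrix of unit normals.
#' @export
landmark_normals <- function(shape) {
  n <- nrow(shape)
  prev <- shape[c(n, seq_len(n - 1)), , drop = FALSE]
  nxt <- shape[c(seq_len(n - 1) + 1, 1), , drop = FALSE]
  chord <- nxt - prev
  nrm <- cbind(chord[, 2], -chord[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm / len
}

#' Build per-landmark grey-level profile models
#'
#' For every landmark, collects the normalized gradient profiles over the
#' training images/shapes and stores their mean and covariance. The
#' covariance is regularized by adding \code{delta I} with
#' \code{delta = 1e-6 trace / k} (floored at 1e-8) so the Mahalanobis
#' matching stays well posed even for nearly deterministic training sets.
#'
#' @param imgs List of training intensity matrices.
#' @param shapes List of corresponding n x 2 landmark shapes.
#' @param k Profile half-length.
#' @return An object of class \code{profile_model}: \code{means} (n x
#'   (2k+1) matrix), \code{covs} (list of (2k+1) square matrices),
#'   \code{k}.
#' @export
build_profile_models <- function(imgs, shapes, k = 6) {
  stopifnot(length(imgs) == length(shapes), length(imgs) >= 1)
  n_lm <- nrow(shapes[[1]])
  if (!all(vapply(shapes, nrow, 1L) == n_lm)) {
    stop("inconsistent landmark counts across training shapes")
  }
  m <- 2 * k + 1
  profs <- array(NA_real_, c(length(imgs), n_lm, m))
  for (i in seq_along(imgs)) {
    nrm <- landmark_normals(shapes[[i]])
    for (j in seq_len(n_lm)) {
      profs[i, j, ] <- sample_profile(imgs[[i]], shapes[[i]][j, ], nrm[j, ], k)
    }
  }
  means <- matrix(NA_real_, n_lm, m)
  covs <- vector("list", n_lm)
  for (j in seq_len(n_lm)) {
    P <- profs[, j, , drop = FALSE]
    dim(P) <- c(length(imgs), m)
    means[j, ] <- colMeans(P)
    S <- if (nrow(P) >= 2) stats::cov(P) else matrix(0, m, m)
    delta <- max(1e-6 * sum(diag(S)) / k, 1e-8)
    covs[[j]] <- S + delta * diag(m)
  }
  structure(list(means = means, covs = covs, k = k),
            class = "profile_model")
}

#' Mahalanobis profile cost
#'
#' \eqn{(g - \bar g)^\top S^{-1} (g - \bar g)}, computed by a linear solve.
#'
#' @param profile Sampled profile vector.
#' @param mean_profile Model mean profile of the same length.
#' @param covariance Model covariance matrix.
#' @return Non-negative scalar.
#' @export
mahalanobis_cost <- function(profile, mean_profile, covariance) {
  stopifnot(length(profile) == length(mean_profile),
            all(dim(covariance) == length(profile)))
  d <- profile - mean_profile
  sol <- tryCatch(solve(covariance, d),
                  error = function(e) stop("singular profile covariance: ",
                                           conditionMessage(e)))
  max(0, sum(d * sol))
}

#' One Active Shape Model search step
#'
#' For each landmark, evaluates the \code{2 search_range + 1} candidate
#' positions at unit steps along the landmark normal, proposes the one with
#' the lowest Mahalanobis profile cost (ties break to the smallest
#' displacement), and regularizes the proposed shape through the shape
#' model: pose and clamped mode coefficients are recovered with
#' \code{\link{project_shape}} and the constrained shape regenerated with
#' \code{\link{generate_shape}}.
#'
#' @param img Intensity matrix.
#' @param current Current n x 2 shape.
#' @param shape_model The per-vertebra \code{shape_model}.
#' @param profiles A \code{\link{build_profile_models}} result.
#' @param search_range Candidate half-range in pixels.
#' @return The regularized updated shape; attribute \code{total_cost} holds
#'   the summed best candidate costs.
#' @export
asm_search_step <- function(img, current, shape_model, profiles,
                            search_range = 4) {
  stopifnot(inherits(profiles, "profile_model"),
            nrow(current) == nrow(profiles$means))
  k <- profiles$k
  s <- search_range
  nrm <- landmark_normals(current)
  offsets <- -s:s
  proposed <- current
  total_cost <- 0
  for (j in seq_len(nrow(current))) {
    g_ext <- profile_gradient(img, current[j, ], nrm[j, ], -(k + s):(k + s))
    costs <- vapply(seq_along(offsets), function(oi) {
      win <- normalize_profile(g_ext[oi:(oi + 2 * k)])
      mahalanobis_cost(win, profiles$means[j, ], profiles$covs[[j]])
    }, numeric(1))
    best <- order(costs, abs(offsets), offsets)[1]
    total_cost <- total_cost + costs[best]
    proposed[j, ] <- current[j, ] + offsets[best] * nrm[j, ]
  }
  pr <- project_shape(shape_model, proposed)
  out <- generate_shape(shape_model, pr$b, pr$pose)
  attr(out, "total_cost") <- total_cost
  out
}

#' Active Shape Model segmentation of one vertebra
#'
#' Iterates \code{\link{asm_search_step}} from the initial shape until the
#' mean landmark movement drops below \code{tol} or the summed profile
#' match stops improving, up to \code{max_iter} iterations.
#'
#' @param img Intensity matrix.
#' @param init Initial n x 2 shape (from
#'   \code{\link{init_vertebra_shapes}} or user supplied).
#' @param shape_model The vertebra \code{shape_model}.
#' @param profiles The vertebra \code{profile_model}.
#' @param tol Convergence threshold on mean landmark movement (pixels).
#' @param max_iter Iteration cap.
#' @param search_range Candidate half-range per step.
#' @return An object of class \code{asm_fit}: \code{final_shape},
#'   \code{iterations}, \code{converged}, \code{movement} (per-iteration
#'   mean landmark movement).
#' @export
segment_vertebra <- function(img, init, shape_model, profiles, tol = 0.5,
                             max_iter = 50, search_range = 4) {
  current <- init
  movements <- numeric(0)
  converged <- FALSE
  prev_cost <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    nxt <- asm_search_step(img, current, shape_model, profiles, search_range)
    mv <- mean(sqrt(rowSums((nxt - current)^2)))
    movements <- c(movements, mv)
    cost <- attr(nxt, "total_cost")
    current <- nxt
    if (mv < tol || cost >= prev_cost) {
      converged <- TRUE
      break
    }
    prev_cost <- cost
  }
  attr(current, "total_cost") <- NULL
  structure(list(final_shape = current, iterations = it,
                 converged = converged, movement = movements),
            class = "asm_fit")
}
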