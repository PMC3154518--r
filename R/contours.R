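#' Trace edge contours
#'
#' Converts a binary edge mask into ordered 8-connected point chains by
#' boundary following: chains start preferentially at endpoints (pixels with
#' at most one unvisited neighbour), extend pixel by pixel with 4-adjacent
#' moves preferred over diagonal ones, and stop at chain ends or junctions.
#' A chain whose last point is adjacent to its first is closed (the first
#' point is repeated at the end). Every edge pixel belongs to at most one
#' contour.
#'
#' @param edges Logical edge mask.
#' @param min_length Minimum number of pixels for a chain to be kept.
#' @return A list of contours, each a list with \code{points} (matrix with
#'   columns \code{x} = column, \code{y} = row, 1-based) and \code{closed}.
#' @export
trace_contours <- function(edges, min_length = 10) {
  stopifnot(is.matrix(edges), is.logical(edges))
  nr <- nrow(edges); nc <- ncol(edges)
  unvisited <- edges
  # neighbour moves: 4-adjacent first, deterministic order
  moves <- rbind(c(-1, 0), c(0, -1), c(0, 1), c(1, 0),
                 c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  count_unvisited_nb <- function() {
    cnt <- matrix(0L, nr, nc)
    for (i in seq_len(nrow(moves))) {
      cnt <- cnt + shift_matrix(unvisited, moves[i, 1], moves[i, 2], FALSE)
    }
    cnt
  }
  next_unvisited_nb <- function(r, c) {
    for (i in seq_len(nrow(moves))) {
      rr <- r + moves[i, 1]; cc <- c + moves[i, 2]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && unvisited[rr, cc]) {
        return(c(rr, cc))
      }
    }
    NULL
  }
  contours <- list()
  while (any(unvisited)) {
    cnt <- count_unvisited_nb()
    ends <- which(unvisited & cnt <= 1L)
    start <- if (length(ends)) ends[1] else which(unvisited)[1]
    r <- ((start - 1) %% nr) + 1
    c <- ((start - 1) %/% nr) + 1
    cap <- sum(unvisited)
    pts_r <- integer(cap); pts_c <- integer(cap)
    n <- 0L
    repeat {
      n <- n + 1L
      pts_r[n] <- r; pts_c[n] <- c
      unvisited[r, c] <- FALSE
      nxt <- next_unvisited_nb(r, c)
      if (is.null(nxt)) break
      r <- nxt[1]; c <- nxt[2]
    }
    pts_r <- pts_r[seq_len(n)]; pts_c <- pts_c[seq_len(n)]
    if (n >= min_length) {
      closed <- n >= 3 &&
        max(abs(pts_r[1] - pts_r[n]), abs(pts_c[1] - pts_c[n])) <= 1 &&
        !(pts_r[1] == pts_r[n] && pts_c[1] == pts_c[n])
      pts <- cbind(x = pts_c, y = pts_r)
      if (closed) pts <- rbind(pts, pts[1, ])
      contours[[length(contours) + 1]] <- list(points = pts, closed = closed)
    }
  }
  contours
}

# distance from each row of pts to the segment a-b (clamped projection)
dist_to_segment <- function(pts, a, b) {
  d <- b - a
  len2 <- sum(d^2)
  if (len2 == 0) {
    return(sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2))
  }
  t <- ((pts[, 1] - a[1]) * d[1] + (pts[, 2] - a[2]) * d[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((pts[, 1] - (a[1] + t * d[1]))^2 + (pts[, 2] - (a[2] + t * d[2]))^2)
}

dp_open <- function(pts, epsilon) {
  n <- nrow(pts)
  keep <- logical(n)
  keep[c(1, n)] <- TRUE
  stack <- list(c(1, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    if (j - i < 2) next
    mid <- (i + 1):(j - 1)
    d <- dist_to_segment(pts[mid, , drop = FALSE], pts[i, ], pts[j, ])
    kmax <- which.max(d)  # ties: lowest index
    if (d[kmax] > epsilon) {
      a <- mid[kmax]
      keep[a] <- TRUE
      stack[[length(stack) + 1]] <- c(i, a)
      stack[[length(stack) + 1]] <- c(a, j)
    }
  }
  which(keep)
}

#' Douglas-Peucker polygonal approximation
#'
#' Recursive polyline simplification: the farthest interior point from the
#' chord joining the polyline extremities is retained (and the rule recursed
#' on both halves) whenever its distance exceeds \code{epsilon}; otherwise
#' all interior points are removed. Distances are measured to the chord
#' segment. Ties for the farthest point break to the lowest index. Closed
#' contours are split at their two mutually farthest points and each half is
#' approximated as an open polyline.
#'
#' @param contour A contour from \code{\link{trace_contours}}, or a plain
#'   two-column point matrix (treated as an open polyline).
#' @param epsilon Distance threshold in pixels (>= 0).
#' @return An object of class \code{polyline_approx}: \code{vertices} (point
#'   matrix), \code{indices} (into the contour's points), \code{epsilon} and
#'   \code{closed}.
#' @export
douglas_peucker <- function(contour, epsilon) {
  if (is.matrix(contour)) contour <- list(points = contour, closed = FALSE)
  pts <- contour$points
  stopifnot(epsilon >= 0)
  if (nrow(pts) < 2) stop("contour must have at least 2 points")
  if (isTRUE(contour$closed)) {
    ring <- pts[-nrow(pts), , drop = FALSE]  # drop duplicated first point
    m <- nrow(ring)
    if (m < 3) {
      idx <- seq_len(m)
    } else {
      fp <- farthest_pair(ring)
      s1 <- fp[1]; s2 <- fp[2]
      half1 <- s1:s2
      half2 <- c(s2:m, 1:s1)
      k1 <- half1[dp_open(ring[half1, , drop = FALSE], epsilon)]
      k2 <- half2[dp_open(ring[half2, , drop = FALSE], epsilon)]
      idx <- sort(unique(c(k1, k2)))
    }
    structure(list(vertices = ring[idx, , drop = FALSE], indices = idx,
                   epsilon = epsilon, closed = TRUE),
              class = "polyline_approx")
  } else {
    idx <- dp_open(pts, epsilon)
    structure(list(vertices = pts[idx, , drop = FALSE], indices = idx,
                   epsilon = epsilon, closed = FALSE),
              class = "polyline_approx")
  }
}

# indices of the two mutually farthest points of a small point set
farthest_pair <- function(pts) {
  m <- nrow(pts)
  if (m <= 4000) {
    dmat <- as.matrix(stats::dist(pts))
    ij <- which(dmat == max(dmat), arr.ind = TRUE)
    ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
    sort(c(ij[1, 1], ij[1, 2]))
  } else {
    # two-sweep diameter heuristic for very long rings
    d1 <- (pts[, 1] - pts[1, 1])^2 + (pts[, 2] - pts[1, 2])^2
    p <- which.max(d1)
    d2 <- (pts[, 1] - pts[p, 1])^2 + (pts[, 2] - pts[p, 2])^2
    sort(c(p, which.max(d2)))
  }
}

# turning angle (degrees, 0 = straight) at v given previous u and next w
turning_angle <- function(u, v, w) {
  a <- v - u; b <- w - v
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  cosang <- sum(a * b) / (na * nb)
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Corner detection by polygonal approximation
#'
#' Approximates each contour with \code{\link{douglas_peucker}} and emits the
#' interior vertices whose turning angle (deviation from a straight
#' continuation) lies in \code{[min_angle, max_angle]} — the geometric
#' definition of a corner as the intersection of two segment lines, with
#' near-collinear vertices and noise spikes filtered out.
#'
#' @param contours List of contours from \code{\link{trace_contours}}.
#' @param epsilon Douglas-Peucker threshold in pixels (> 0).
#' @param min_angle,max_angle Turning-angle band in degrees.
#' @return An object of class \code{corner_set}: a data frame with columns
#'   \code{x}, \code{y} and \code{contour} (provenance index).
#' @export
detect_corners <- function(contours, epsilon = 4, min_angle = 30,
                           max_angle = 150) {
  stopifnot(epsilon > 0)
  rows <- list()
  for (ci in seq_along(contours)) {
    ct <- contours[[ci]]
    if (nrow(ct$points) < 3) next
    ap <- douglas_peucker(ct, epsilon)
    v <- ap$vertices
    m <- nrow(v)
    if (ap$closed) {
      if (m < 3) next
      interior <- seq_len(m)
      prev_i <- c(m, seq_len(m - 1)); next_i <- c(seq_len(m - 1) + 1, 1)
    } else {
      if (m < 3) next
      interior <- 2:(m - 1)
      prev_i <- seq_len(m) - 1; next_i <- seq_len(m) + 1
    }
    for (i in interior) {
      ang <- turning_angle(v[prev_i[i], ], v[i, ], v[next_i[i], ])
      if (ang >= min_angle && ang <= max_angle) {
        rows[[length(rows) + 1]] <- c(v[i, 1], v[i, 2], ci)
      }
    }
  }
  df <- if (length(rows)) {
    m <- do.call(rbind, rows)
    data.frame(x = m[, 1], y = m[, 2], contour = as.integer(m[, 3]))
  } else {
    data.frame(x = numeric(0), y = numeric(0), contour = integer(0))
  }
  structure(df, class = c("corner_set", "data.frame"))
}
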