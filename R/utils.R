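# Shared helpers.

#' @useDynLib rootarch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Seed the RNG locally; returns the previous .Random.seed (or NULL).
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Euclidean arc length of an n x 2 polyline matrix.
polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

# Resample an n x 2 polyline at (approximately) equal arc-length steps,
# always keeping both endpoints.
resample_polyline <- function(pts, step) {
  if (nrow(pts) < 2) return(pts)
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) return(pts[c(1, nrow(pts)), , drop = FALSE])
  n <- max(2L, as.integer(ceiling(total / step)) + 1L)
  s <- seq(0, total, length.out = n)
  x <- stats::approx(cum, pts[, 1], xout = s, ties = "ordered")$y
  y <- stats::approx(cum, pts[, 2], xout = s, ties = "ordered")$y
  cbind(x, y)
}

# Minimum distance from point p = c(x, y) to a polyline (n x 2).
point_polyline_dist <- function(p, pts) {
  if (nrow(pts) == 1) return(sqrt(sum((p - pts[1, ])^2)))
  a <- pts[-nrow(pts), , drop = FALSE]
  b <- pts[-1, , drop = FALSE]
  v <- b - a
  len2 <- rowSums(v^2)
  w <- cbind(p[1] - a[, 1], p[2] - a[, 2])
  t <- ifelse(len2 > 0, (w[, 1] * v[, 1] + w[, 2] * v[, 2]) / len2, 0)
  t <- pmin(pmax(t, 0), 1)
  dx <- w[, 1] - t * v[, 1]
  dy <- w[, 2] - t * v[, 2]
  sqrt(min(dx^2 + dy^2))
}
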