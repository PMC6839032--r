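# Loss functions: median-frequency class-balanced binary cross-entropy for
# the segmentation branch, weighted mean squared error for the heat-map
# branch, summed without extra scaling.

#' Median-frequency class balancing weights
#'
#' For each class `c`, `freq(c)` is the number of pixels of class `c` across
#' the training set divided by the total number of pixels in the images that
#' contain that class. The weight is `alpha_c = median(freq) / freq(c)`, so
#' frequent classes (background) are down-weighted and rare classes
#' (second-order roots) up-weighted.
#'
#' @param masks list of ground-truth class-map arrays `(H, W, 3)` with binary
#'   channels ordered (background, first-order, second-order).
#' @return list with `freq`, `median_freq` and `alpha` (all length 3, named).
#' @export
class_balance_weights <- function(masks) {
  classes <- c("background", "order1", "order2")
  pix <- numeric(3)
  present_pix <- numeric(3)
  for (m in masks) {
    npix <- prod(dim(m)[1:2])
    for (k in 1:3) {
      cnt <- sum(m[, , k] > 0.5)
      if (cnt > 0) {
        pix[k] <- pix[k] + cnt
        present_pix[k] <- present_pix[k] + npix
      }
    }
  }
  if (any(pix == 0))
    stop("undefined class frequency: class(es) ",
         paste(classes[pix == 0], collapse = ", "),
         " absent from every image")
  freq <- pix / present_pix
  med <- stats::median(freq)
  alpha <- med / freq
  names(freq) <- names(alpha) <- classes
  list(freq = freq, median_freq = med, alpha = alpha)
}

check_loss_shapes <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("loss shape mismatch")
  invisible(NULL)
}

#' Segmentation loss (class-balanced binary cross-entropy)
#'
#' `L1 = -(1/N) * sum_n alpha_n * sum_xy [g log ghat + (1-g) log(1-ghat)]`,
#' where `n` runs over the `N` class channels and `alpha_n` is the
#' median-frequency balancing weight of channel `n`. The negation makes the
#' minimized loss non-negative. Predictions are clamped away from {0,1}
#' before the logarithms. Batched inputs are averaged over the batch.
#'
#' @param g ground-truth binary class maps `(H, W, N)` or `(H, W, N, B)`.
#' @param ghat predicted per-channel sigmoid activations, same shape.
#' @param alpha per-channel weights (length `N`), default all 1.
#' @return scalar loss.
#' @export
seg_loss <- function(g, ghat, alpha = NULL) {
  check_loss_shapes(g, ghat)
  d <- dim(g)
  if (length(d) == 3L) { dim(g) <- c(d, 1L); dim(ghat) <- c(d, 1L); d <- dim(g) }
  N <- d[3]; B <- d[4]
  if (is.null(alpha)) alpha <- rep(1, N)
  if (length(alpha) != N) stop("alpha must have one weight per channel")
  eps <- 1e-7
  gh <- pmin(pmax(ghat, eps), 1 - eps)
  ll <- g * log(gh) + (1 - g) * log(1 - gh)
  aw <- aperm(array(alpha, dim = c(N, d[1], d[2], B)), c(2, 3, 1, 4))
  -sum(aw * ll) / N / B
}

# Gradient of seg_loss w.r.t. the pre-sigmoid logits (used in training):
# d L1 / d logits = alpha/(N*B) * (sigmoid(logits) - g).
seg_loss_grad_logits <- function(g, sig, alpha, B) {
  d <- dim(g)
  N <- d[3]
  aw <- aperm(array(alpha, dim = c(N, d[1], d[2], d[4])), c(2, 3, 1, 4))
  aw * (sig - g) / N / B
}

#' Heat-map regression loss (weighted mean squared error)
#'
#' `L2 = (1/N) * sum_n alpha_n * sum_xy (p - phat)^2` over the `N` heat-map
#' channels; `alpha` defaults to 1 for every channel. Batched inputs are
#' averaged over the batch.
#'
#' @param p ground-truth heat maps `(H, W, N)` or `(H, W, N, B)`.
#' @param phat predictions, same shape.
#' @param alpha optional per-channel weights.
#' @return scalar loss.
#' @export
heat_loss <- function(p, phat, alpha = NULL) {
  check_loss_shapes(p, phat)
  d <- dim(p)
  if (length(d) == 3L) { dim(p) <- c(d, 1L); dim(phat) <- c(d, 1L); d <- dim(p) }
  N <- d[3]; B <- d[4]
  if (is.null(alpha)) alpha <- rep(1, N)
  if (length(alpha) != N) stop("alpha must have one weight per channel")
  aw <- aperm(array(alpha, dim = c(N, d[1], d[2], B)), c(2, 3, 1, 4))
  sum(aw * (p - phat)^2) / N / B
}

heat_loss_grad <- function(p, phat, alpha, B) {
  d <- dim(p)
  N <- d[3]
  aw <- aperm(array(alpha, dim = c(N, d[1], d[2], d[4])), c(2, 3, 1, 4))
  2 * aw * (phat - p) / N / B
}

#' Total multi-task loss
#'
#' `L = L1 + L2`, with no additional scaling factors between the two
#' branches.
#'
#' @param l1 segmentation loss.
#' @param l2 heat-map loss.
#' @return scalar.
#' @export
total_loss <- function(l1, l2) l1 + l2
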