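# Post-processing: optional dense-CRF refinement of the segmentation, then
# extraction of discrete feature points from the heat maps by scanline
# non-maximal suppression followed by spatial-index deduplication.

#' Dense CRF refinement of segmentation probabilities
#'
#' Mean-field inference for a fully connected CRF with Potts compatibility
#' and two Gaussian pairwise kernels: an appearance (bilateral) kernel over
#' position and colour and a smoothness kernel over position. The bilateral
#' message is computed over a strided truncated window (an approximation of
#' the dense kernel; see the methods vignette). With `enabled = FALSE` the
#' input is returned unchanged.
#'
#' @param seg_probs array `(H, W, 3)` of class probabilities, normalised
#'   across classes at every pixel.
#' @param image array `(H, W, 3)` in `[0, 1]` (the input image at the same
#'   resolution).
#' @param iters mean-field iterations (default 5).
#' @param sxy_app,srgb appearance kernel spatial / colour standard
#'   deviations (defaults 30 px and 13/255).
#' @param w_app,w_sm kernel weights.
#' @param sxy_sm smoothness kernel spatial standard deviation (default 3 px).
#' @param enabled set `FALSE` to switch the stage off (identity).
#' @return refined probabilities, same shape, still normalised.
#' @export
crf_refine <- function(seg_probs, image, iters = 5L, sxy_app = 30,
                       srgb = 13 / 255, w_app = 4, w_sm = 2, sxy_sm = 3,
                       enabled = TRUE) {
  if (!enabled) return(seg_probs)
  stopifnot(length(dim(seg_probs)) == 3L, length(dim(image)) == 3L)
  stride <- max(1L, as.integer(floor(sxy_app / 5)))
  cpp_crf_meanfield(seg_probs, image, as.integer(iters), sxy_app, srgb,
                    w_app, sxy_sm, w_sm, stride)
}

#' Non-maximal suppression peaks of a heat-map channel
#'
#' Scanline 3x3 NMS: pixels below `threshold` are discounted immediately; a
#' remaining pixel is suppressed if any pixel of greater (or equal, if
#' scanned earlier in row-major order) intensity lies in its 3x3
#' neighbourhood. For an isolated Gaussian this returns the peak pixel.
#'
#' @param channel numeric matrix `(H, W)` with values in `[0, 1]`.
#' @param threshold detection threshold (default 0.7).
#' @return data frame with `x`, `y` (0-based pixel coordinates) and `score`,
#'   in scan order.
#' @export
nms_peaks <- function(channel, threshold = 0.7) {
  m <- cpp_nms_scan(channel, threshold)
  data.frame(x = m[, 2] - 1, y = m[, 1] - 1, score = m[, 3])
}

#' Deduplicate feature points with a spatial index
#'
#' Greedy insertion in scan order: each candidate is queried against a
#' grid-bucket spatial index of already-kept points and discarded if any kept
#' point lies within `radius` pixels.
#'
#' @param points data frame with `x`, `y` (and optionally `score`), in scan
#'   order.
#' @param radius deduplication radius in pixels (default 8).
#' @return the kept subset, original order preserved.
#' @export
dedup_points <- function(points, radius = 8) {
  n <- nrow(points)
  if (n == 0) return(points)
  cell <- radius
  index <- new.env(parent = emptyenv())
  keep <- logical(n)
  for (i in seq_len(n)) {
    px <- points$x[i]; py <- points$y[i]
    cx <- floor(px / cell); cy <- floor(py / cell)
    clash <- FALSE
    for (gx in (cx - 1):(cx + 1)) {
      for (gy in (cy - 1):(cy + 1)) {
        key <- paste0(gx, ",", gy)
        bucket <- index[[key]]
        if (!is.null(bucket)) {
          for (j in bucket) {
            if ((points$x[j] - px)^2 + (points$y[j] - py)^2 <= radius^2) {
              clash <- TRUE
              break
            }
          }
        }
        if (clash) break
      }
      if (clash) break
    }
    if (!clash) {
      keep[i] <- TRUE
      key <- paste0(cx, ",", cy)
      index[[key]] <- c(index[[key]], i)
    }
  }
  points[keep, , drop = FALSE]
}

#' Localize seed and tip features from heat maps
#'
#' Applies [nms_peaks()] and [dedup_points()] to each heat-map channel.
#' If no seed is detected a warning is raised (downstream reconstruction
#' will return an empty architecture).
#'
#' @param heats array `(H, W, 3)` with channels `(seed, tip1, tip2)`.
#' @param threshold NMS threshold (default 0.7).
#' @param radius deduplication radius (default 8).
#' @return object of class `feature_set`: list of data frames `seeds`,
#'   `tips1`, `tips2`.
#' @export
localize_features <- function(heats, threshold = 0.7, radius = 8) {
  fs <- list(
    seeds = dedup_points(nms_peaks(heats[, , 1], threshold), radius),
    tips1 = dedup_points(nms_peaks(heats[, , 2], threshold), radius),
    tips2 = dedup_points(nms_peaks(heats[, , 3], threshold), radius))
  class(fs) <- "feature_set"
  if (nrow(fs$seeds) == 0)
    warning("no seed locations detected; architecture will be empty")
  fs
}

#' Write a feature set to CSV
#'
#' @param fs a `feature_set`.
#' @param path output CSV path.
#' @export
write_features_csv <- function(fs, path) {
  rows <- do.call(rbind, lapply(c("seeds", "tips1", "tips2"), function(k) {
    d <- fs[[k]]
    if (nrow(d) == 0) return(NULL)
    data.frame(class = k, x = d$x, y = d$y, score = d$score)
  }))
  if (is.null(rows)) rows <- data.frame(class = character(0), x = numeric(0),
                                        y = numeric(0), score = numeric(0))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
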