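# Conversion of a root system into training targets: binary per-class
# segmentation masks (strokes of a fixed width, no anti-aliasing) and
# feature heat maps (unit-peak Gaussians of standard deviation 1 px at the
# seed and at first-/second-order root tips).

#' Render per-class segmentation masks
#'
#' Each root is drawn as a hard (non-anti-aliased) polyline stroke of
#' `stroke_width` pixels into the channel matching its order. Where first-
#' and second-order strokes cross, the pixel is set in both class channels;
#' the background channel is the complement of their union.
#'
#' @param rs a `root_system` with coordinates in the target pixel frame
#'   (use [scale_root_system()] to move between resolutions).
#' @param shape `c(H, W)` of the output grids.
#' @param stroke_width stroke width in pixels (default 8).
#' @return array `(H, W, 3)` with binary channels
#'   `(background, order1, order2)` and class `"class_maps"` attribute.
#' @export
render_class_masks <- function(rs, shape, stroke_width = 8) {
  H <- shape[1]; W <- shape[2]
  hw <- stroke_width / 2
  seg1 <- root_segments(rs, 1L)
  seg2 <- root_segments(rs, 2L)
  o1 <- if (nrow(seg1) > 0) cpp_stroke_segments(H, W, seg1, hw, FALSE) else matrix(0, H, W)
  o2 <- if (nrow(seg2) > 0) cpp_stroke_segments(H, W, seg2, hw, FALSE) else matrix(0, H, W)
  bg <- 1 - pmax(o1, o2)
  array(c(bg, o1, o2), dim = c(H, W, 3))
}

# Feature points of a root system: seed, first-order tips, second-order tips
# (a root's tip is the last point of its polyline).
feature_points <- function(rs) {
  seeds <- do.call(rbind, lapply(rs$plants, function(pl) pl$seed))
  t1 <- list(); t2 <- list()
  for (pl in rs$plants)
    for (rt in pl$roots) {
      tip <- rt$points[nrow(rt$points), ]
      if (rt$order == 1L) t1[[length(t1) + 1L]] <- tip else t2[[length(t2) + 1L]] <- tip
    }
  list(seeds = if (is.null(seeds)) matrix(numeric(0), 0, 2) else seeds,
       tips1 = if (length(t1)) do.call(rbind, t1) else matrix(numeric(0), 0, 2),
       tips2 = if (length(t2)) do.call(rbind, t2) else matrix(numeric(0), 0, 2))
}

add_gaussian <- function(grid, x, y, sigma) {
  H <- nrow(grid); W <- ncol(grid)
  rad <- ceiling(4 * sigma)
  cx <- round(x); cy <- round(y)
  cols <- max(0, cx - rad):min(W - 1, cx + rad)
  rows <- max(0, cy - rad):min(H - 1, cy + rad)
  if (length(cols) == 0 || length(rows) == 0) return(grid)
  g <- exp(-(outer((rows - y)^2, (cols - x)^2, "+")) / (2 * sigma^2))
  grid[rows + 1, cols + 1] <- grid[rows + 1, cols + 1] + g
  grid
}

#' Render feature heat maps
#'
#' For each seed, first-order tip and second-order tip, a unit-peak Gaussian
#' of standard deviation `sigma` pixels is added to the corresponding
#' channel; overlapping Gaussians are clamped at 1.
#'
#' @param rs a `root_system` in the target pixel frame.
#' @param shape `c(H, W)`.
#' @param sigma Gaussian standard deviation in pixels (default 1).
#' @return array `(H, W, 3)` with channels `(seed, tip1, tip2)` in `[0, 1]`.
#' @export
render_heatmaps <- function(rs, shape, sigma = 1.0) {
  H <- shape[1]; W <- shape[2]
  fp <- feature_points(rs)
  chans <- list(fp$seeds, fp$tips1, fp$tips2)
  out <- array(0, dim = c(H, W, 3))
  for (k in 1:3) {
    g <- matrix(0, H, W)
    pts <- chans[[k]]
    if (nrow(pts) > 0)
      for (i in seq_len(nrow(pts)))
        g <- add_gaussian(g, pts[i, 1], pts[i, 2], sigma)
    out[, , k] <- pmin(g, 1)
  }
  out
}

#' Export class maps or heat maps as 8-bit PNG files
#'
#' One grayscale PNG per channel, for visual inspection.
#'
#' @param maps array `(H, W, C)` with values in `[0, 1]`.
#' @param prefix file path prefix; channel names are appended.
#' @param nms channel name suffixes (default `ch1..chC`).
#' @return invisibly, the written paths.
#' @export
write_map_pngs <- function(maps, prefix,
                           nms = paste0("ch", seq_len(dim(maps)[3]))) {
  paths <- character(0)
  for (k in seq_len(dim(maps)[3])) {
    p <- paste0(prefix, "_", nms[k], ".png")
    png::writePNG(clamp01(maps[, , k]), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
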