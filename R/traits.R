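# Per-plant phenotypic traits measured on a root system: maximum depth,
# maximum width, convex hull area, centroid depth, per-order root counts and
# total lengths.

shoelace_area <- function(pts) {
  n <- nrow(pts)
  if (n < 3) return(0)
  x <- pts[, 1]; y <- pts[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Compute per-plant phenotypic traits
#'
#' Definitions (pixel units unless `mm_per_px` is given):
#' * `max_depth`: max over first-order tips of `tip_y - seed_y` (depends
#'   only on the seed and the lowest first-order tip).
#' * `max_width`: `max_x - min_x` over all root points of all orders.
#' * `convex_hull_area`: area of the 2D convex hull of all root points.
#' * `centroid_depth`: mean `y` of all roots' uniformly resampled points
#'   minus `seed_y` (long roots weigh proportionally to their length).
#' * `n_roots_order1`, `n_roots_order2`: counts.
#' * `total_length_order1`, `total_length_order2`: summed polyline arc
#'   lengths per order.
#'
#' @param rs a `root_system`.
#' @param resample_step arc-length step (px) for point-based traits
#'   (default 2).
#' @param mm_per_px optional scale; lengths are multiplied by it and areas
#'   by its square.
#' @return data frame, one row per plant, with a `flag` column set to
#'   `"no_roots"` for plants without roots (all-zero row).
#' @export
compute_traits <- function(rs, resample_step = 2, mm_per_px = NULL) {
  rows <- lapply(seq_along(rs$plants), function(pi) {
    pl <- rs$plants[[pi]]
    if (length(pl$roots) == 0)
      return(data.frame(plant = pi, max_depth = 0, max_width = 0,
                        convex_hull_area = 0, centroid_depth = 0,
                        n_roots_order1 = 0, n_roots_order2 = 0,
                        total_length_order1 = 0, total_length_order2 = 0,
                        flag = "no_roots"))
    ord <- vapply(pl$roots, function(r) r$order, integer(1))
    tips1_y <- vapply(pl$roots[ord == 1L], function(r)
      r$points[nrow(r$points), 2], numeric(1))
    all_pts <- do.call(rbind, lapply(pl$roots, function(r) r$points))
    res_pts <- do.call(rbind, lapply(pl$roots, function(r)
      resample_polyline(r$points, resample_step)))
    lens <- vapply(pl$roots, function(r) polyline_length(r$points), numeric(1))
    hull <- grDevices::chull(all_pts)
    data.frame(
      plant = pi,
      max_depth = if (length(tips1_y)) max(tips1_y) - pl$seed[2] else 0,
      max_width = max(all_pts[, 1]) - min(all_pts[, 1]),
      convex_hull_area = shoelace_area(all_pts[hull, , drop = FALSE]),
      centroid_depth = mean(res_pts[, 2]) - pl$seed[2],
      n_roots_order1 = sum(ord == 1L),
      n_roots_order2 = sum(ord == 2L),
      total_length_order1 = sum(lens[ord == 1L]),
      total_length_order2 = sum(lens[ord == 2L]),
      flag = "")
  })
  out <- do.call(rbind, rows)
  if (!is.null(mm_per_px)) {
    for (col in c("max_depth", "max_width", "centroid_depth",
                  "total_length_order1", "total_length_order2"))
      out[[col]] <- out[[col]] * mm_per_px
    out$convex_hull_area <- out$convex_hull_area * mm_per_px^2
  }
  out
}

#' Write a trait table to CSV
#'
#' @param traits data frame from [compute_traits()].
#' @param path output path.
#' @param image_id optional image identifier column value.
#' @export
write_traits_csv <- function(traits, path, image_id = NA_character_) {
  traits <- cbind(image = image_id, traits)
  utils::write.csv(traits, path, row.names = FALSE)
  invisible(path)
}
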