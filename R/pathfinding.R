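# Root architecture reconstruction: class-aware weighted pixel graphs built
# from distance transforms of the segmentation masks, traversed by A* (single
# seed) or Dijkstra-to-set (multiple goals) searches from tips back to seeds
# (first order) or to already-extracted first-order paths (second order).

WEIGHT_ON_MIN <- 0.01
WEIGHT_ON_MAX <- 0.1
WEIGHT_OFF <- 10.0

#' Normalized distance map of a class mask
#'
#' Euclidean distance transform of the foreground to the nearest background
#' pixel, normalized to `[0, 1]` per connected foreground component (each
#' component's maximum distance maps to 1, so thin and thick roots in one
#' image both retain a full-range centering signal). Background pixels are 0.
#'
#' @param mask binary matrix `(H, W)` (non-zero = foreground).
#' @return numeric matrix in `[0, 1]`.
#' @export
distance_map <- function(mask) {
  m <- matrix(as.numeric(mask > 0.5), nrow(mask), ncol(mask))
  if (!any(m > 0)) return(m)
  # pad with a background ring so outside-image counts as background (also
  # covers the all-foreground case)
  mp <- matrix(0, nrow(m) + 2, ncol(m) + 2)
  mp[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  d <- EBImage::distmap(mp, metric = "euclidean")
  d <- d[2:(nrow(m) + 1), 2:(ncol(m) + 1)]
  lab <- EBImage::bwlabel(m)
  out <- matrix(0, nrow(m), ncol(m))
  for (k in seq_len(max(lab))) {
    sel <- lab == k
    mx <- max(d[sel])
    out[sel] <- if (mx > 0) d[sel] / mx else 1
  }
  out
}

#' Traversal weight map
#'
#' On-class pixels get `w = 0.1 - 0.09 * dist` (0.1 at the root edge,
#' decreasing linearly to 0.01 at the centerline); off-class pixels get 10.0.
#' Diagonal steps are additionally weighted by `sqrt(2)` at search time.
#'
#' @param dist normalized distance map from [distance_map()].
#' @param mask the binary class mask the distances were computed from.
#' @return numeric matrix of per-pixel traversal costs.
#' @export
weight_map <- function(dist, mask) {
  on <- mask > 0.5
  w <- matrix(WEIGHT_OFF, nrow(mask), ncol(mask))
  w[on] <- WEIGHT_ON_MAX - (WEIGHT_ON_MAX - WEIGHT_ON_MIN) * dist[on]
  w
}

points_to_goal_mask <- function(H, W, pts) {
  g <- matrix(FALSE, H, W)
  if (nrow(pts) > 0) {
    r <- pmin(pmax(round(pts[, 2]) + 1, 1), H)
    c <- pmin(pmax(round(pts[, 1]) + 1, 1), W)
    g[cbind(r, c)] <- TRUE
  }
  g
}

#' A* search on a weighted pixel lattice
#'
#' Minimal-cost 8-connected path from `start` to the goal set, where
#' stepping onto pixel `q` costs `weights[q]` (times `sqrt(2)` for diagonal
#' steps), expanding lowest `f = g + h` first. The Manhattan-distance
#' heuristic is scaled by the minimum per-step weight (0.01) so it never
#' overestimates the true remaining cost, keeping the returned cost optimal.
#' With more than one goal the heuristic is dropped (uniform-cost search).
#'
#' @param weights matrix of per-pixel traversal costs.
#' @param start `c(x, y)` 0-based start pixel.
#' @param goals n x 2 matrix of 0-based goal pixels (or a logical mask).
#' @param heuristic_scale scale applied to the Manhattan heuristic (default
#'   `0.01`, the minimum on-class weight).
#' @return list with `path` (m x 2 matrix of 0-based `(x, y)`, start to
#'   goal) and `cost`.
#' @export
astar <- function(weights, start, goals,
                  heuristic_scale = WEIGHT_ON_MIN) {
  H <- nrow(weights); W <- ncol(weights)
  gm <- if (is.matrix(goals) && is.logical(goals)) goals
        else points_to_goal_mask(H, W, rbind(goals))
  if (!any(gm)) stop("empty goal set")
  res <- cpp_grid_search(weights, round(start[2]) + 1, round(start[1]) + 1,
                         gm, heuristic_scale, sqrt(2))
  list(path = cbind(x = res$path[, 2] - 1, y = res$path[, 1] - 1),
       cost = res$cost)
}

#' Dijkstra search to a goal set
#'
#' Uniform-cost search (no remaining-distance heuristic) terminating at the
#' first settled goal, which is therefore the goal with the shortest
#' possible path from `start`.
#'
#' @inheritParams astar
#' @return list with `path` and `cost` as in [astar()].
#' @export
dijkstra_to_set <- function(weights, start, goals) {
  astar(weights, start, goals, heuristic_scale = 0)
}

# Fraction of a path's cost contributed by off-class pixels.
offclass_cost_fraction <- function(weights, path) {
  if (nrow(path) < 2) return(0)
  idx <- cbind(path[-1, 2] + 1, path[-1, 1] + 1)
  steps <- weights[idx]
  diag <- (abs(diff(path[, 1])) + abs(diff(path[, 2]))) == 2
  steps <- steps * ifelse(diag, sqrt(2), 1)
  sum(steps[weights[idx] >= WEIGHT_OFF]) / max(sum(steps), 1e-12)
}

#' Reconstruct a root system from class maps and localized features
#'
#' One candidate plant is created per detected seed. Each first-order tip is
#' traced over the first-order weight graph to the seed set (A* with the
#' scaled Manhattan heuristic when there is exactly one seed, Dijkstra to
#' the set otherwise) and assigned to the plant of the seed it reaches. Each
#' second-order tip is then traced over the second-order graph with the
#' pixels of all extracted first-order paths as goals, and attached to the
#' owning first-order root at the reached pixel. Plants whose seed attracted
#' no first-order root are removed. Paths are found tip-to-seed and reversed
#' so polylines run base to tip.
#'
#' Roots whose path cost is dominated by off-class (weight 10.0) pixels are
#' flagged in an attribute `offclass_flagged` (a logging aid, never a
#' filter).
#'
#' @param class_maps array `(H, W, 3)` `(background, order1, order2)`;
#'   probabilistic maps are thresholded at 0.5.
#' @param features a `feature_set` from [localize_features()].
#' @param offclass_warn_frac flag threshold for the off-class cost fraction
#'   (default 0.3).
#' @return a `root_system` (coordinates in the class-map pixel frame).
#' @export
reconstruct <- function(class_maps, features, offclass_warn_frac = 0.3) {
  H <- dim(class_maps)[1]; W <- dim(class_maps)[2]
  empty <- structure(list(plants = list(), image_size = c(W, H),
                          style = "reconstructed"), class = "root_system")
  seeds <- features$seeds
  if (nrow(seeds) == 0) {
    warning("zero seeds: returning empty root system")
    return(empty)
  }
  m1 <- class_maps[, , 2] > 0.5
  m2 <- class_maps[, , 3] > 0.5
  w1 <- weight_map(distance_map(m1), m1)
  w2 <- weight_map(distance_map(m2), m2)

  plants <- lapply(seq_len(nrow(seeds)), function(i)
    list(seed = c(seeds$x[i], seeds$y[i]), roots = list()))
  seed_mask <- points_to_goal_mask(H, W, cbind(seeds$x, seeds$y))
  flagged <- list()

  # first-order roots: tip -> seed set
  single_seed <- nrow(seeds) == 1
  for (i in seq_len(nrow(features$tips1))) {
    tip <- c(features$tips1$x[i], features$tips1$y[i])
    res <- if (single_seed)
      astar(w1, tip, cbind(seeds$x[1], seeds$y[1]))
    else
      dijkstra_to_set(w1, tip, seed_mask)
    end <- res$path[nrow(res$path), ]
    d2seed <- (seeds$x - end[1])^2 + (seeds$y - end[2])^2
    pid <- which.min(d2seed)
    pts <- res$path[rev(seq_len(nrow(res$path))), , drop = FALSE]  # base -> tip
    if (offclass_cost_fraction(w1, res$path) > offclass_warn_frac)
      flagged[[length(flagged) + 1L]] <- c(order = 1, plant = pid)
    plants[[pid]]$roots[[length(plants[[pid]]$roots) + 1L]] <-
      list(order = 1L, points = pts, parent = NA_integer_, attachment = NULL)
  }

  # second-order roots: tip -> any first-order path pixel
  o1_goal <- matrix(FALSE, H, W)
  owner <- array(NA_integer_, dim = c(H, W, 2))  # plant id, root id
  for (pid in seq_along(plants))
    for (rid in seq_along(plants[[pid]]$roots)) {
      pts <- plants[[pid]]$roots[[rid]]$points
      r <- pmin(pmax(round(pts[, 2]) + 1, 1), H)
      c <- pmin(pmax(round(pts[, 1]) + 1, 1), W)
      o1_goal[cbind(r, c)] <- TRUE
      owner[cbind(r, c, 1)] <- pid
      owner[cbind(r, c, 2)] <- rid
    }
  if (any(o1_goal)) {
    for (i in seq_len(nrow(features$tips2))) {
      tip <- c(features$tips2$x[i], features$tips2$y[i])
      res <- dijkstra_to_set(w2, tip, o1_goal)
      end <- res$path[nrow(res$path), ]
      pid <- owner[end[2] + 1, end[1] + 1, 1]
      rid <- owner[end[2] + 1, end[1] + 1, 2]
      pts <- res$path[rev(seq_len(nrow(res$path))), , drop = FALSE]
      if (offclass_cost_fraction(w2, res$path) > offclass_warn_frac)
        flagged[[length(flagged) + 1L]] <- c(order = 2, plant = pid)
      plants[[pid]]$roots[[length(plants[[pid]]$roots) + 1L]] <-
        list(order = 2L, points = pts, parent = rid,
             attachment = c(end[1], end[2]))
    }
  }

  # prune plants that attracted no first-order root
  has_o1 <- vapply(plants, function(pl)
    any(vapply(pl$roots, function(rt) rt$order == 1L, logical(1))), logical(1))
  plants <- plants[has_o1]
  rs <- structure(list(plants = plants, image_size = c(W, H),
                       style = "reconstructed"), class = "root_system")
  attr(rs, "offclass_flagged") <- flagged
  rs
}
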