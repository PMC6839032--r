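# Shared fixture builders. Everything is generated in code at test time.

tiny_fibrous_params <- function(seed = 1L, ...) {
  architecture_params(style = "fibrous", image_size = 256L, root_width = 6,
                      n_first_order = c(3L, 3L),
                      laterals_per_root = c(1L, 2L), rng_seed = seed, ...)
}

tiny_taproot_params <- function(seed = 1L, n_plants = 3L, image_size = 384L,
                                ...) {
  architecture_params(style = "taproot", n_plants = n_plants,
                      image_size = image_size, root_width = 6,
                      laterals_per_root = c(2L, 4L), rng_seed = seed, ...)
}

# Independent shortest-path oracle via igraph: directed 8-connected lattice
# where the edge into pixel q costs weights[q] (times diag_factor for
# diagonal moves). start/goals are 0-based (x, y).
igraph_grid_cost <- function(weights, start, goals, diag_factor = sqrt(2)) {
  H <- nrow(weights); W <- ncol(weights)
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- max(1, 1 - dr):min(H, H - dr)   # source rows with valid target
    cs <- max(1, 1 - dc):min(W, W - dc)
    src <- as.vector(outer(rs, (cs - 1) * H, "+"))
    tgt <- as.vector(outer(rs + dr, (cs + dc - 1) * H, "+"))
    fac <- if (abs(dr) + abs(dc) == 2) diag_factor else 1
    tr <- ((tgt - 1) %% H) + 1
    tc <- ((tgt - 1) %/% H) + 1
    from <- c(from, src)
    to <- c(to, tgt)
    wt <- c(wt, fac * weights[cbind(tr, tc)])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
  igraph::E(g)$weight <- wt
  sv <- start[1] * H + start[2] + 1          # (c-1)*H + r with r=y+1, c=x+1
  gv <- goals[, 1] * H + goals[, 2] + 1
  d <- igraph::distances(g, v = sv, to = gv, mode = "out")
  min(d)
}

# Exhaustive convex hull area: test all point pairs as candidate hull edges
# (all other points strictly on one side), then shoelace on the polygon.
brute_hull_area <- function(pts) {
  pts <- unique(round(pts, 9))
  n <- nrow(pts)
  if (n < 3) return(0)
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    v <- pts[j, ] - pts[i, ]
    cr <- (pts[, 1] - pts[i, 1]) * v[2] - (pts[, 2] - pts[i, 2]) * v[1]
    if (all(cr <= 1e-9) || all(cr >= -1e-9)) {
      on_hull[i] <- TRUE
      on_hull[j] <- TRUE
    }
  }
  hp <- pts[on_hull, , drop = FALSE]
  ctr <- colMeans(hp)
  ord <- order(atan2(hp[, 2] - ctr[2], hp[, 1] - ctr[1]))
  hp <- hp[ord, , drop = FALSE]
  x <- hp[, 1]; y <- hp[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}
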