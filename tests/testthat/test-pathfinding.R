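# Distance/weight maps and the lattice searches driving reconstruction.

test_that("distance map contracts: background zero, interior normalized to 1", {
  expect_true(all(distance_map(matrix(0, 16, 16)) == 0))
  allfg <- distance_map(matrix(1, 16, 16))
  expect_equal(max(allfg), 1)
  # 8-px horizontal band: center rows maximal, monotone from edge to center
  m <- matrix(0, 32, 32)
  m[13:20, ] <- 1
  d <- distance_map(m)
  mid <- d[16:17, 16]
  expect_equal(max(d[, 16]), max(mid))
  col <- d[13:16, 16]
  expect_true(all(diff(col) >= 0))
  # brute-force nearest-background oracle on a small grid
  m2 <- matrix(0, 12, 12)
  m2[4:8, 3:10] <- 1
  d2 <- distance_map(m2)
  bg <- which(m2 == 0, arr.ind = TRUE)
  raw <- matrix(0, 12, 12)
  for (r in 4:8) for (c in 3:10)
    raw[r, c] <- min(sqrt((bg[, 1] - r)^2 + (bg[, 2] - c)^2))
  expect_equal(d2, raw / max(raw), tolerance = 1e-6)
})

test_that("weight map hits the printed endpoints", {
  mask <- matrix(1, 4, 4)
  dist <- matrix(0, 4, 4)
  dist[2, 2] <- 1
  w <- weight_map(dist, mask)
  expect_equal(w[2, 2], 0.01)          # centerline
  expect_equal(w[1, 1], 0.1)           # root edge
  w2 <- weight_map(matrix(0, 2, 2), matrix(0, 2, 2))
  expect_true(all(w2 == 10))           # off-class
})

test_that("a start inside the goal set costs zero", {
  w <- matrix(1, 8, 8)
  res <- astar(w, c(3, 3), cbind(3, 3))
  expect_equal(res$cost, 0)
  expect_equal(nrow(res$path), 1)
  expect_error(astar(w, c(1, 1), matrix(FALSE, 8, 8)), "empty goal")
})

test_that("the search follows a cheap corridor and matches the igraph oracle", {
  skip_if_not_installed("igraph")
  H <- 24; W <- 100
  w <- matrix(10, H, W)
  w[11:13, ] <- 0.1
  w[12, ] <- 0.01                       # centerline
  res <- astar(w, c(0, 11), cbind(99, 11))
  expect_true(all(res$path[, 2] == 11)) # stays on the center row
  oracle <- igraph_grid_cost(w, c(0, 11), cbind(99, 11))
  expect_equal(res$cost, oracle, tolerance = 1e-9)
})

test_that("A* cost equals Dijkstra and the igraph oracle on random grids", {
  skip_if_not_installed("igraph")
  set.seed(17)
  for (i in 1:20) {
    w <- matrix(exp(stats::rnorm(32 * 32, 0, 1.2)), 32, 32)
    start <- c(sample(0:31, 1), sample(0:31, 1))
    goal <- c(sample(0:31, 1), sample(0:31, 1))
    a <- astar(w, start, rbind(goal), heuristic_scale = min(w))
    d <- dijkstra_to_set(w, start, rbind(goal))
    expect_equal(a$cost, d$cost, tolerance = 1e-12)
    expect_equal(a$cost, igraph_grid_cost(w, start, rbind(goal)),
                 tolerance = 1e-9)
  }
})

test_that("Dijkstra to a set stops at the cheaper goal", {
  w <- matrix(1, 10, 10)
  w[, 6:10] <- 5                        # right half is expensive
  goals <- rbind(c(2, 5), c(9, 5))      # left goal reachable cheaply
  res <- dijkstra_to_set(w, c(4, 5), goals)
  endp <- res$path[nrow(res$path), ]
  expect_equal(unname(endp), c(2, 5))
  # singleton goal set: identical to A*
  a <- astar(w, c(0, 0), rbind(c(9, 9)))
  d <- dijkstra_to_set(w, c(0, 0), rbind(c(9, 9)))
  expect_equal(a$cost, d$cost)
})

test_that("reconstruction recovers counts and geometry from oracle maps", {
  p <- architecture_params("fibrous", image_size = 384L, root_width = 8,
                           n_first_order = c(3L, 3L),
                           laterals_per_root = c(1L, 2L), rng_seed = 31L)
  rs <- generate_architecture(p)
  maps <- render_class_masks(rs, c(384, 384), stroke_width = 8)
  heats <- render_heatmaps(rs, c(384, 384))
  fs <- localize_features(heats)
  rec <- reconstruct(maps, fs)
  expect_length(rec$plants, 1)
  expect_equal(rootarch:::count_roots(rec, 1L), rootarch:::count_roots(rs, 1L))
  expect_equal(rootarch:::count_roots(rec, 2L), rootarch:::count_roots(rs, 2L))
  # every recovered first-order polyline stays near a true centerline
  true_o1 <- Filter(function(r) r$order == 1L, rs$plants[[1]]$roots)
  for (rt in Filter(function(r) r$order == 1L, rec$plants[[1]]$roots)) {
    devs <- vapply(seq_len(nrow(rt$points)), function(i)
      min(vapply(true_o1, function(tr)
        rootarch:::point_polyline_dist(rt$points[i, ], tr$points),
        numeric(1))), numeric(1))
    expect_lt(mean(devs), 2)
  }
  # polylines run base (near seed) to tip
  for (rt in Filter(function(r) r$order == 1L, rec$plants[[1]]$roots))
    expect_lt(sqrt(sum((rt$points[1, ] - rec$plants[[1]]$seed)^2)), 10)
})

test_that("plants whose seed attracts no first-order root are pruned", {
  maps <- array(0, dim = c(64, 64, 3))
  maps[, , 2][31:33, 5:60] <- 1   # one horizontal first-order root
  maps[, , 1] <- 1 - maps[, , 2]
  fs <- structure(list(
    seeds = data.frame(x = c(4, 40), y = c(31, 10), score = 1),
    tips1 = data.frame(x = 59, y = 31, score = 1),
    tips2 = data.frame(x = numeric(0), y = numeric(0), score = numeric(0))),
    class = "feature_set")
  rec <- reconstruct(maps, fs)
  expect_length(rec$plants, 1)
  expect_equal(unname(rec$plants[[1]]$seed), c(4, 31))
})

test_that("no tips means no plants; no seeds warns and returns empty", {
  maps <- array(0, dim = c(32, 32, 3))
  maps[, , 1] <- 1
  fs <- structure(list(
    seeds = data.frame(x = 10, y = 10, score = 1),
    tips1 = data.frame(x = numeric(0), y = numeric(0), score = numeric(0)),
    tips2 = data.frame(x = numeric(0), y = numeric(0), score = numeric(0))),
    class = "feature_set")
  expect_length(reconstruct(maps, fs)$plants, 0)
  fs$seeds <- fs$tips1
  expect_warning(rec <- reconstruct(maps, fs), "zero seeds")
  expect_length(rec$plants, 0)
})
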