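# Feature localization (NMS + deduplication) and dense-CRF refinement.

gauss_channel <- function(H, W, centers, amp = 1, sigma = 1) {
  g <- matrix(0, H, W)
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1]; cy <- centers[i, 2]
    for (r in max(1, cy - 4):min(H, cy + 6))
      for (c in max(1, cx - 4):min(W, cx + 6))
        g[r, c] <- g[r, c] +
          amp * exp(-(((r - 1) - cy)^2 + ((c - 1) - cx)^2) / (2 * sigma^2))
  }
  pmin(g, 1)
}

test_that("NMS returns nothing on an empty map and the peak of a Gaussian", {
  expect_equal(nrow(nms_peaks(matrix(0, 64, 64))), 0)
  ch <- gauss_channel(128, 128, cbind(100, 100))
  pk <- nms_peaks(ch, 0.7)
  expect_equal(nrow(pk), 1)
  expect_equal(c(pk$x, pk$y), c(100, 100))
})

test_that("peaks below the 0.7 threshold are never returned", {
  ch <- gauss_channel(64, 64, cbind(30, 30), amp = 0.6)
  expect_equal(nrow(nms_peaks(ch, 0.7)), 0)
  expect_equal(nrow(nms_peaks(ch, 0.5)), 1)
})

test_that("two well-separated Gaussians give two peaks within 1 px", {
  ch <- gauss_channel(96, 96, rbind(c(20, 40), c(50, 40)))
  pk <- nms_peaks(ch, 0.7)
  expect_equal(nrow(pk), 2)
  d <- pmin(sqrt((pk$x - 20)^2 + (pk$y - 40)^2),
            sqrt((pk$x - 50)^2 + (pk$y - 40)^2))
  expect_true(all(d <= 1))
})

test_that("equal-valued plateau keeps only the first pixel in scan order", {
  ch <- matrix(0, 16, 16)
  ch[8, 8:9] <- 0.9   # two equal neighbours in one row
  pk <- nms_peaks(ch, 0.7)
  expect_equal(nrow(pk), 1)
  expect_equal(c(pk$x, pk$y), c(7, 7))  # 0-based (x, y) of the earlier pixel
})

test_that("deduplication keeps the first of a close pair and both of a far pair", {
  expect_equal(nrow(dedup_points(data.frame(x = numeric(0), y = numeric(0)))), 0)
  near <- data.frame(x = c(10, 13), y = c(10, 14), score = c(1, 0.9))
  kept <- dedup_points(near, radius = 8)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$x, 10)
  far <- data.frame(x = c(10, 19), y = c(10, 10), score = c(1, 0.9))
  expect_equal(nrow(dedup_points(far, radius = 8)), 2)
})

test_that("tip pairs 6 px apart collapse to a single feature", {
  ch <- gauss_channel(64, 64, rbind(c(30, 30), c(36, 30)))
  heats <- array(0, dim = c(64, 64, 3))
  heats[, , 2] <- ch
  fs <- suppressWarnings(localize_features(heats))
  expect_equal(nrow(fs$tips1), 1)
})

test_that("feature localization recovers a generated system's features exactly", {
  p <- tiny_fibrous_params(seed = 21L)
  rs <- generate_architecture(p)
  heats <- render_heatmaps(rs, c(256, 256))
  fs <- localize_features(heats)
  expect_equal(nrow(fs$seeds), 1)
  expect_equal(nrow(fs$tips1), rootarch:::count_roots(rs, 1L))
  expect_equal(nrow(fs$tips2), rootarch:::count_roots(rs, 2L))
  # every returned point within 1 px of a planted tip
  fp <- rootarch:::feature_points(rs)
  for (i in seq_len(nrow(fs$tips1))) {
    d <- sqrt((fp$tips1[, 1] - fs$tips1$x[i])^2 +
              (fp$tips1[, 2] - fs$tips1$y[i])^2)
    expect_lte(min(d), 1)
  }
  expect_warning(localize_features(array(0, dim = c(32, 32, 3))), "no seed")
})

test_that("CRF refinement is the identity when disabled", {
  set.seed(1)
  probs <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  expect_identical(crf_refine(probs, img, enabled = FALSE), probs)
})

test_that("CRF barely changes a uniformly confident segmentation", {
  H <- 64
  probs <- array(0.01, dim = c(H, H, 3))
  probs[, , 1] <- 0.98
  img <- array(0.5, dim = c(H, H, 3))
  out <- crf_refine(probs, img, sxy_app = 10)
  before <- apply(probs, c(1, 2), which.max)
  after <- apply(out, c(1, 2), which.max)
  expect_lt(mean(before != after), 0.001)
  # output still normalized
  expect_true(all(abs(apply(out, c(1, 2), sum) - 1) < 1e-6))
})

test_that("CRF suppresses isolated salt-and-pepper foreground pixels", {
  set.seed(8)
  H <- 64
  probs <- array(0, dim = c(H, H, 3))
  probs[, , 1] <- 0.9
  probs[, , 2] <- 0.05
  probs[, , 3] <- 0.05
  img <- array(0.4, dim = c(H, H, 3))
  idx <- sample(H * H, 40)  # ~1% isolated foreground
  flip <- matrix(c(0.2, 0.75, 0.05), nrow = 1)
  for (i in idx) {
    r <- ((i - 1) %% H) + 1; c <- ((i - 1) %/% H) + 1
    probs[r, c, ] <- flip
  }
  count_isolated <- function(pr) {
    lab <- apply(pr, c(1, 2), which.max) == 2
    n <- 0
    for (r in 2:(H - 1)) for (c in 2:(H - 1))
      if (lab[r, c] && sum(lab[(r - 1):(r + 1), (c - 1):(c + 1)]) == 1)
        n <- n + 1
    n
  }
  n0 <- count_isolated(probs)
  out <- crf_refine(probs, img, sxy_app = 10)
  expect_gt(n0, 0)
  expect_lt(count_isolated(out), n0)
})
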