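# Loss functions and median-frequency class balancing.

test_that("uniform class frequencies give unit weights", {
  # three images where each class covers half the pixels it appears in
  m <- array(0, dim = c(4, 4, 3))
  m[, 1:2, 1] <- 1
  m[, 3:4, 2] <- 1
  m[1:2, 3:4, 3] <- 0  # order2 absent here
  m2 <- m
  m2[, , 3] <- m[, , 2]
  m2[, , 2] <- m[, , 1]
  m2[, , 1] <- m[, , 3]
  m2[, 1:2, 1] <- 1  # keep background present
  bal <- class_balance_weights(list(m, m2))
  expect_named(bal$alpha, c("background", "order1", "order2"))
  expect_true(all(bal$freq > 0))
  # direct identity: alpha = median / freq
  expect_equal(unname(bal$alpha), unname(bal$median_freq / bal$freq))
})

test_that("the printed example frequencies give the expected weights", {
  # freq = (0.9, 0.08, 0.02) -> median 0.08 -> alpha = (0.0889, 1, 4)
  freq <- c(0.9, 0.08, 0.02)
  alpha <- stats::median(freq) / freq
  expect_equal(alpha, c(0.0889, 1.0, 4.0), tolerance = 1e-3)
})

test_that("a class absent from every image raises an error", {
  m <- array(0, dim = c(4, 4, 3))
  m[, , 1] <- 1
  m[1, 1, 2] <- 1
  expect_error(class_balance_weights(list(m)), "order2")
})

test_that("segmentation loss is zero at a perfect prediction and matches hand values", {
  g <- array(rbinom(48, 1, 0.4), dim = c(4, 4, 3))
  expect_lt(seg_loss(g, g), 1e-5)                 # clamped perfect prediction
  # single pixel, single effective channel: -log(0.5)
  g1 <- array(0, dim = c(1, 1, 3))
  gh <- array(0, dim = c(1, 1, 3))
  g1[1, 1, 1] <- 1
  gh[1, 1, 1] <- 0.5
  gh[1, 1, 2:3] <- 1e-9                            # no contribution
  expect_equal(seg_loss(g1, gh, alpha = c(3, 0, 0)), -log(0.5),
               tolerance = 1e-6)
  # doubling a channel weight doubles that channel's contribution
  set.seed(2)
  ghat <- array(runif(48, 0.1, 0.9), dim = c(4, 4, 3))
  l_a <- seg_loss(g, ghat, alpha = c(1, 1, 1))
  l_b <- seg_loss(g, ghat, alpha = c(1, 2, 1))
  only2 <- seg_loss(g, ghat, alpha = c(0, 1, 0))
  expect_equal(l_b - l_a, only2, tolerance = 1e-10)
})

test_that("with unit weights the segmentation loss equals plain binary cross-entropy", {
  set.seed(3)
  g <- array(rbinom(30, 1, 0.5), dim = c(5, 2, 3))
  ghat <- array(runif(30, 0.05, 0.95), dim = c(5, 2, 3))
  bce <- -sum(g * log(ghat) + (1 - g) * log(1 - ghat)) / 3
  expect_equal(seg_loss(g, ghat), bce, tolerance = 1e-9)
})

test_that("heat loss matches hand values and is non-negative", {
  p <- array(0, dim = c(1, 1, 3))
  ph <- array(0, dim = c(1, 1, 3))
  ph[1, 1, 1] <- 0.5
  expect_equal(heat_loss(p, ph, alpha = c(3, 1, 1)), 0.25, tolerance = 1e-12)
  expect_equal(heat_loss(p, p), 0)
  set.seed(4)
  a <- array(runif(75), dim = c(5, 5, 3))
  b <- array(runif(75), dim = c(5, 5, 3))
  expect_gte(heat_loss(a, b), 0)
})

test_that("the total loss is the unweighted sum of both branch losses", {
  expect_equal(total_loss(0.3, 0.2), 0.5)
  expect_equal(total_loss(0, 0), 0)
})

test_that("gradient of the total loss is the sum of per-head gradients", {
  # finite differences on a 2-pixel toy batch
  set.seed(5)
  g <- array(rbinom(12, 1, 0.5), dim = c(2, 1, 3, 2))
  p <- array(runif(12), dim = c(2, 1, 3, 2))
  logits <- array(rnorm(12), dim = c(2, 1, 3, 2))
  phat <- array(runif(12), dim = c(2, 1, 3, 2))
  alpha <- c(0.2, 1, 3)
  sig <- 1 / (1 + exp(-logits))
  gs <- rootarch:::seg_loss_grad_logits(g, sig, alpha, 2)
  gh <- rootarch:::heat_loss_grad(p, phat, rep(1, 3), 2)
  eps <- 1e-6
  for (i in c(1, 7, 12)) {
    l2p <- logits; l2p[i] <- logits[i] + eps
    l2m <- logits; l2m[i] <- logits[i] - eps
    tot <- function(lg, ph) total_loss(seg_loss(g, 1 / (1 + exp(-lg)), alpha),
                                       heat_loss(p, ph))
    fd_seg <- (tot(l2p, phat) - tot(l2m, phat)) / (2 * eps)
    expect_equal(gs[i], fd_seg, tolerance = 1e-5)
    hp <- phat; hp[i] <- phat[i] + eps
    hm <- phat; hm[i] <- phat[i] - eps
    fd_heat <- (tot(logits, hp) - tot(logits, hm)) / (2 * eps)
    expect_equal(gh[i], fd_heat, tolerance = 1e-5)
  }
})

test_that("the fused training loss kernel equals the R loss functions", {
  set.seed(7)
  logits <- array(rnorm(8 * 8 * 3 * 2), dim = c(8, 8, 3, 2))
  heat <- array(runif(8 * 8 * 3 * 2), dim = c(8, 8, 3, 2))
  g <- array(rbinom(8 * 8 * 3 * 2, 1, .3), dim = c(8, 8, 3, 2))
  p <- array(runif(8 * 8 * 3 * 2), dim = c(8, 8, 3, 2))
  al <- c(.2, 1, 3)
  # elementwise per-pixel-class weights, as the trainer builds them
  wseg <- rootarch:::pixel_class_weights(g, al)
  lo <- rootarch:::ft_multitask_loss(rootarch:::ft_from_array(logits),
                                     rootarch:::ft_from_array(heat),
                                     g, p, wseg, rep(1, 3))
  # independent R evaluation of the weighted cross-entropy
  sig <- pmin(pmax(1 / (1 + exp(-logits)), 1e-7), 1 - 1e-7)
  ref <- -sum(wseg * (g * log(sig) + (1 - g) * log(1 - sig))) / 3 / 2
  expect_equal(lo$l1, ref, tolerance = 1e-5)
  expect_equal(lo$l2, heat_loss(p, heat), tolerance = 1e-5)
  # with unit weights the kernel reduces to the per-channel loss
  lo1 <- rootarch:::ft_multitask_loss(rootarch:::ft_from_array(logits),
                                      rootarch:::ft_from_array(heat),
                                      g, p, array(1, dim(g)), rep(1, 3))
  expect_equal(lo1$l1, seg_loss(g, 1 / (1 + exp(-logits))), tolerance = 1e-5)
})

test_that("shape mismatches are rejected", {
  expect_error(seg_loss(array(0, c(2, 2, 3)), array(0, c(2, 3, 3))))
  expect_error(heat_loss(array(0, c(2, 2, 3)), array(0, c(3, 2, 3))))
})
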