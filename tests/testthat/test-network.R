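# Network construction, parameter counting, forward-pass contracts, and
# agreement with the naive double-precision reference implementation.

test_that("a single 1x1 convolution counts weights plus biases", {
  ly <- rootarch:::layer_conv(1L, 128L, 3L, bias = TRUE)
  expect_equal(sum(lengths(lapply(ly$params, function(p) p$v))), 128 * 3 + 3)
})

test_that("the full-width network has the reference parameter count", {
  m <- build_network(network_spec(1))
  expect_identical(count_parameters(m), 1595782)
})

test_that("width-0.5 parameter count matches a layer-by-layer hand count", {
  # independent arithmetic: conv = k^2*cin*cout (+cout), bn = 2c,
  # bottleneck(cin, p, cout) with biased convs and projection on change
  cv <- function(k, ci, co, b = TRUE) k * k * ci * co + if (b) co else 0
  bn <- function(c) 2 * c
  bneck <- function(ci, p, co) {
    s <- bn(ci) + cv(1, ci, p) + bn(p) + cv(3, p, p) + bn(p) + cv(1, p, co)
    if (ci != co) s <- s + cv(1, ci, co)
    s
  }
  s32 <- 32; c64 <- 64; c128 <- 128; p16 <- 16; p32 <- 32
  expected <- cv(7, 3, s32, FALSE) + bn(s32) +
    bneck(s32, p16, c64) + bneck(c64, p16, c64) + bneck(c64, p32, c128) +
    12 * bneck(c128, p32, c128) +
    cv(1, c128, c128) + bn(c128) +
    cv(2, c128, c128, FALSE) + bn(c128) + bneck(c128, p32, c128) +
    cv(2, c128, c64, FALSE) + bn(c64) + bneck(c64, p16, c64) +
    cv(1, c64, c64) +
    2 * (cv(1, c64, c64) + cv(1, c64, 3))
  m <- build_network(network_spec(0.5))
  expect_identical(count_parameters(m), expected)
})

test_that("the model is fully convolutional: output is half the input size", {
  m <- build_network(network_spec(0.125, hourglass_depth = 2L), rng_seed = 1)
  for (side in c(64L, 96L)) {
    x <- array(runif(side * side * 3), dim = c(side, side, 3, 1))
    out <- net_predict(m, x)
    expect_equal(dim(out$seg_prob), c(side / 2, side / 2, 3, 1))
    expect_equal(dim(out$heat), c(side / 2, side / 2, 3, 1))
  }
  expect_error(net_predict(m, array(0, dim = c(50, 50, 3, 1))), "divisible")
})

test_that("parameter count does not depend on hourglass input resolution", {
  # same spec, two different valid input sizes through the same model
  m <- build_network(network_spec(0.125, hourglass_depth = 2L), rng_seed = 2)
  n0 <- count_parameters(m)
  invisible(net_predict(m, array(0.5, dim = c(64, 64, 3, 1))))
  invisible(net_predict(m, array(0.5, dim = c(128, 128, 3, 1))))
  expect_identical(count_parameters(m), n0)
})

test_that("softmax class probabilities sum to 1 at every pixel", {
  m <- build_network(network_spec(0.125, hourglass_depth = 2L), rng_seed = 3)
  out <- net_predict(m, array(runif(64 * 64 * 3), dim = c(64, 64, 3, 1)))
  sums <- apply(out$seg_prob, c(1, 2, 4), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
})

test_that("forward pass agrees with the naive reference implementation", {
  spec <- network_spec(0.1, hourglass_depth = 1L)
  m <- build_network(spec, rng_seed = 3)
  set.seed(1)
  x <- array(runif(16 * 16 * 3 * 2), dim = c(16, 16, 3, 2))
  out <- rootarch:::model_forward(m, x, training = TRUE)
  ref <- ref_forward(m, x)
  expect_lt(max(abs(rootarch:::ft_to_array(out$seg$v) - ref$seg)), 1e-3)
  expect_lt(max(abs(rootarch:::ft_to_array(out$heat$v) - ref$heat)), 1e-3)
})

test_that("backpropagated gradients match finite differences of the reference", {
  spec <- network_spec(0.1, hourglass_depth = 1L)
  m <- build_network(spec, rng_seed = 3)
  for (b in m$bnorms) b$momentum <- 0
  set.seed(1)
  alpha <- c(0.1, 1, 4)
  x <- array(runif(16 * 16 * 3 * 2), dim = c(16, 16, 3, 2))
  g <- array(rbinom(8 * 8 * 3 * 2, 1, 0.3), dim = c(8, 8, 3, 2))
  p <- array(runif(8 * 8 * 3 * 2), dim = c(8, 8, 3, 2))
  out <- rootarch:::model_forward(m, x, training = TRUE)
  aw <- aperm(array(alpha, dim = c(3, 8, 8, 2)), c(2, 3, 1, 4))
  lo <- rootarch:::ft_multitask_loss(out$seg$v, out$heat$v, g, p, aw,
                                     rep(1, 3))
  rootarch:::param_zero_grad(m$params)
  out$seg$g <- lo$gseg
  out$heat$g <- lo$gheat
  rootarch:::tape_run_backward(out$tape)
  ref_loss <- function() {
    r <- ref_forward(m, x)
    seg_loss(g, 1 / (1 + exp(-r$seg)), alpha) + heat_loss(p, r$heat)
  }
  eps <- 1e-5
  set.seed(5)
  for (pi in sample(seq_along(m$params), 6)) {
    prm <- m$params[[pi]]
    j <- which.max(abs(prm$g))
    v0 <- prm$v[j]
    prm$v[j] <- v0 + eps
    lp <- ref_loss()
    prm$v[j] <- v0 - eps
    lm <- ref_loss()
    prm$v[j] <- v0
    fd <- (lp - lm) / (2 * eps)
    expect_equal(prm$g[j], fd, tolerance = 1e-2)
  }
})

test_that("checkpoints round-trip weights and running statistics", {
  spec <- network_spec(0.1, hourglass_depth = 1L)
  m <- build_network(spec, rng_seed = 7)
  x <- array(runif(16 * 16 * 3 * 2), dim = c(16, 16, 3, 2))
  invisible(rootarch:::model_forward(m, x, training = TRUE))  # move BN stats
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  y1 <- net_predict(m, array(runif(16 * 16 * 3), dim = c(16, 16, 3, 1)))
  # identical weights + stats => identical eval output on the same input
  set.seed(99)
  xi <- array(runif(16 * 16 * 3), dim = c(16, 16, 3, 1))
  expect_identical(net_predict(m, xi), net_predict(m2, xi))
  # loading into a structurally different model errors
  m3 <- build_network(network_spec(0.2, hourglass_depth = 1L))
  expect_error(load_checkpoint(path, into = m3), "shape mismatch|length mismatch")
})

test_that("invalid width multipliers are rejected", {
  expect_error(network_spec(0), "positive")
  expect_error(network_spec(-1), "positive")
})
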