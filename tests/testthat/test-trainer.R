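# Training loop mechanics: schedule, augmentation, channel handling,
# checkpoint selection and the optimization itself on a small run.

test_that("the learning rate drops by 10x at the configured iteration", {
  cfg <- train_config()
  expect_equal(lr_schedule(0, cfg), 1e-4)
  expect_equal(lr_schedule(49999, cfg), 1e-4)
  expect_equal(lr_schedule(50000, cfg), 1e-5)
  expect_equal(lr_schedule(499999, cfg), 1e-5)
})

test_that("grayscale images are duplicated into three identical channels", {
  g <- matrix(0.4, 8, 8)
  rgb <- gray_to_rgb(g)
  expect_equal(dim(rgb), c(8, 8, 3))
  expect_true(all(rgb == 0.4))
  expect_identical(gray_to_rgb(rgb), rgb)      # 3-channel passes through
  g1 <- array(0.7, dim = c(8, 8, 1))
  expect_equal(dim(gray_to_rgb(g1)), c(8, 8, 3))
})

test_that("augmentation with no flip and zero rotation is the identity", {
  set.seed(1)
  img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  masks <- array(rbinom(16 * 16 * 3, 1, 0.2), dim = c(16, 16, 3))
  heats <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  out <- augment(img, masks, heats, flip_prob = 0, rotation_range = c(0, 0))
  expect_identical(out$image, img)
  expect_identical(out$masks, masks)
  expect_identical(out$heats, heats)
})

test_that("a horizontal flip maps column x to W-1-x in image and heat map alike", {
  img <- array(0, dim = c(32, 32, 3))
  img[10, 5, 1] <- 1
  heats <- array(0, dim = c(16, 16, 3))
  heats[8, 3, 2] <- 1   # tip at x = 2 (0-based)
  masks <- array(0, dim = c(16, 16, 3))
  masks[, , 1] <- 1
  out <- augment(img, masks, heats, flip_prob = 1, rotation_range = c(0, 0))
  expect_equal(out$image[10, 32 - 5 + 1, 1], 1)
  expect_equal(out$heats[8, 16 - 3 + 1, 2], 1)   # x' = W-1-x = 13 -> col 14
})

test_that("augmentation is deterministic under a fixed RNG seed", {
  img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  masks <- array(rbinom(16 * 16 * 3, 1, 0.2), dim = c(16, 16, 3))
  heats <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  set.seed(42)
  a <- augment(img, masks, heats)
  set.seed(42)
  b <- augment(img, masks, heats)
  expect_identical(a, b)
  # masks stay binary with a consistent background complement
  expect_true(all(a$masks %in% c(0, 1)))
  expect_true(all(a$masks[, , 1] + pmax(a$masks[, , 2], a$masks[, , 3]) == 1))
})

test_that("zero iterations returns the model unchanged", {
  m <- build_network(network_spec(0.1, hourglass_depth = 1L), rng_seed = 4)
  w0 <- m$params[[1]]$v
  res <- train(m, list(list()), list(list()),
               train_config(max_iterations = 0L))
  expect_identical(res$model$params[[1]]$v, w0)
})

test_that("transfer learning copies weights exactly at zero iterations and rejects mismatched heads", {
  spec <- network_spec(0.1, hourglass_depth = 1L)
  base <- build_network(spec, rng_seed = 5)
  res <- transfer_learn(base, list(), list(),
                        train_config(max_iterations = 0L))
  for (i in seq_along(base$params))
    expect_identical(res$model$params[[i]]$v, base$params[[i]]$v)
  # a 4-class head cannot receive 3-class weights
  spec4 <- spec
  spec4$n_classes <- 4L
  other <- build_network(spec4, rng_seed = 5)
  expect_error(rootarch:::load_state(other, rootarch:::model_state(base)),
               "shape mismatch")
})

test_that("a short training run reduces the loss and returns the best-validation weights", {
  ds <- make_training_set(16, rng_seed = 500, style = "fibrous",
                          image_size = 128L, n_first_order = c(2L, 3L),
                          laterals_per_root = c(1L, 2L), root_width = 6)
  tr <- ds[1:12]
  va <- ds[13:16]
  cfg <- train_config(max_iterations = 200L, validation_interval = 50L,
                      rng_seed = 2)
  m <- build_network(network_spec(0.25), rng_seed = 2)
  res <- train(m, tr, va, cfg)
  h <- res$history
  expect_lt(h$loss[200], h$loss[1])
  expect_true(all(is.finite(h$loss)))
  # the returned weights reproduce the reported best validation accuracy
  expect_equal(rootarch:::validate_model(res$model, va), res$best_val,
               tolerance = 1e-12)
  # reproducibility: same seeds, same trajectory
  m2 <- build_network(network_spec(0.25), rng_seed = 2)
  res2 <- train(m2, tr, va, train_config(max_iterations = 5L,
                                         validation_interval = 5L,
                                         rng_seed = 2))
  m3 <- build_network(network_spec(0.25), rng_seed = 2)
  res3 <- train(m3, tr, va, train_config(max_iterations = 5L,
                                         validation_interval = 5L,
                                         rng_seed = 2))
  expect_equal(res2$history$loss, res3$history$loss, tolerance = 1e-10)
})

test_that("training configuration round-trips through YAML", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("lr0: 2.0e-4", "batch_size: 4", "max_iterations: 10",
               "flip_prob: 0.25"), path)
  cfg <- read_train_config(path)
  expect_equal(cfg$lr0, 2e-4)
  expect_equal(cfg$batch_size, 4L)
  expect_equal(cfg$flip_prob, 0.25)
  expect_equal(cfg$optimizer, "rmsprop")
})
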