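# Training loop: RMSprop on the joint loss L = L1 + L2 with a single
# learning-rate drop, random flip/rotation augmentation, periodic validation
# (class-average pixel accuracy) and best-on-validation checkpointing.
# Transfer learning reuses the same loop from an existing model's weights.

#' Training configuration
#'
#' @param lr0 initial learning rate (default 1e-4).
#' @param lr_drop_factor factor by which the learning rate is reduced
#'   (default 10).
#' @param lr_drop_at iteration at which the drop occurs (default 50000).
#' @param batch_size minibatch size (default 6).
#' @param max_iterations total training iterations (default 500000; the
#'   transfer-learning protocol caps this at 120000).
#' @param flip_prob horizontal-flip probability (default 0.5).
#' @param rotation_range rotation range in degrees (default `c(-30, 30)`).
#' @param validation_interval iterations between validation passes.
#' @param rng_seed seed controlling shuffling, augmentation and
#'   initialisation order.
#' @param rmsprop_alpha,rmsprop_eps optimizer smoothing constant and epsilon.
#' @param heat_alpha optional per-channel weights for the heat-map loss
#'   (default all 1).
#' @return object of class `ra_train_config`.
#' @export
train_config <- function(lr0 = 1e-4, lr_drop_factor = 10, lr_drop_at = 50000L,
                         batch_size = 6L, max_iterations = 500000L,
                         flip_prob = 0.5, rotation_range = c(-30, 30),
                         validation_interval = 100L, rng_seed = 1L,
                         rmsprop_alpha = 0.99, rmsprop_eps = 1e-8,
                         heat_alpha = NULL) {
  stopifnot(lr0 > 0, lr_drop_factor > 0, lr_drop_at > 0, batch_size >= 1,
            max_iterations >= 0, flip_prob >= 0, flip_prob <= 1)
  cfg <- list(optimizer = "rmsprop", lr0 = lr0,
              lr_drop_factor = lr_drop_factor,
              lr_drop_at = as.integer(lr_drop_at),
              batch_size = as.integer(batch_size),
              max_iterations = as.integer(max_iterations),
              flip_prob = flip_prob, rotation_range = rotation_range,
              validation_interval = as.integer(validation_interval),
              rng_seed = as.integer(rng_seed),
              rmsprop_alpha = rmsprop_alpha, rmsprop_eps = rmsprop_eps,
              heat_alpha = heat_alpha)
  class(cfg) <- "ra_train_config"
  cfg
}

#' Read a training configuration from a YAML file
#'
#' @param path YAML file whose keys match [train_config()] arguments.
#' @return a `ra_train_config`.
#' @export
read_train_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(train_config, vals)
}

#' Learning-rate schedule
#'
#' `lr0` until `lr_drop_at` iterations, then `lr0 / lr_drop_factor`.
#'
#' @param iteration 0-based iteration counter.
#' @param config a `ra_train_config`.
#' @return the learning rate.
#' @export
lr_schedule <- function(iteration, config = train_config()) {
  if (iteration < config$lr_drop_at) config$lr0
  else config$lr0 / config$lr_drop_factor
}

#' Duplicate a grayscale channel into 3 RGB channels
#'
#' @param image matrix `(H, W)` or array `(H, W, 1)`; 3-channel input is
#'   passed through unchanged.
#' @return array `(H, W, 3)`.
#' @export
gray_to_rgb <- function(image) {
  d <- dim(image)
  if (length(d) == 3L && d[3] == 3L) return(image)
  if (length(d) == 3L && d[3] == 1L) dim(image) <- d[1:2]
  if (length(dim(image)) != 2L) stop("expected a single-channel image")
  array(rep(image, 3), dim = c(dim(image), 3L))
}

flip_horizontal <- function(a) {
  # reverse the x (column) axis of an (H, W, C) array
  a[, rev(seq_len(dim(a)[2])), , drop = FALSE]
}

#' Random flip/rotation augmentation
#'
#' Applies one geometric transform - horizontal flip with probability
#' `flip_prob`, then rotation by an angle drawn uniformly from
#' `rotation_range` - identically to the image, the class masks and the heat
#' maps (masks and heats may be at a different resolution than the image;
#' the transform is resolution-independent). No random cropping is used.
#' Rotation fills exposed image corners with the image's mean colour;
#' mask/heat corners are filled with 0 and the background mask channel is
#' recomputed as the complement of the root channels.
#'
#' @param image `(H, W, 3)` array.
#' @param masks `(h, w, 3)` binary class maps (background, order1, order2).
#' @param heats `(h, w, 3)` heat maps.
#' @param flip_prob,rotation_range see [train_config()].
#' @return list `(image, masks, heats, flipped, angle)`.
#' @export
augment <- function(image, masks, heats, flip_prob = 0.5,
                    rotation_range = c(-30, 30)) {
  flipped <- stats::runif(1) < flip_prob
  angle <- stats::runif(1, rotation_range[1], rotation_range[2])
  if (flipped) {
    image <- flip_horizontal(image)
    masks <- flip_horizontal(masks)
    heats <- flip_horizontal(heats)
  }
  if (abs(angle) > 1e-9) {
    fill <- colMeans(matrix(image, ncol = dim(image)[3]))
    image <- cpp_rotate_bilinear(image, angle, fill)
    # label masks rotate with nearest sampling: interpolation followed by
    # thresholding erodes strokes only a few pixels wide
    o1 <- cpp_rotate_bilinear(masks[, , 2, drop = FALSE], angle, 0, TRUE)
    o2 <- cpp_rotate_bilinear(masks[, , 3, drop = FALSE], angle, 0, TRUE)
    bg <- 1 - pmax(o1, o2)
    masks <- array(c(bg, o1, o2), dim = dim(masks))
    heats <- clamp01(cpp_rotate_bilinear(heats, angle, 0))
  }
  list(image = image, masks = masks, heats = heats,
       flipped = flipped, angle = angle)
}

# Per-pixel weight map: alpha of each pixel's ground-truth class (highest-
# weight class wins at crossings), replicated across the channel axis.
pixel_class_weights <- function(g, alpha) {
  d <- dim(g)
  w <- array(alpha[1], dim = c(d[1], d[2], d[4]))  # background base
  root <- setdiff(seq_len(d[3]), 1L)
  for (k in root[order(alpha[root])]) {
    sel <- g[, , k, , drop = FALSE] > 0.5
    dim(sel) <- c(d[1], d[2], d[4])
    w[sel] <- alpha[k]
  }
  out <- array(0, dim = d)
  for (k in seq_len(d[3])) out[, , k, ] <- w
  out
}

# Stack a list of (H, W, C) arrays into (H, W, C, B).
stack_batch <- function(lst) {
  d <- dim(lst[[1]])
  array(unlist(lst, use.names = FALSE), dim = c(d, length(lst)))
}

# Class-average pixel accuracy of the segmentation branch on a dataset.
validate_model <- function(model, dataset) {
  correct <- numeric(3)
  total <- numeric(3)
  for (s in dataset) {
    x <- s$image
    dim(x) <- c(dim(x), 1L)
    out <- model_forward(model, x, training = FALSE)
    prob <- softmax_channels(out$seg_array)[, , , 1]
    pred <- apply(prob, c(1, 2), which.max)
    gt <- apply(s$masks, c(1, 2), which.max)
    for (k in 1:3) {
      sel <- gt == k
      total[k] <- total[k] + sum(sel)
      correct[k] <- correct[k] + sum(pred[sel] == k)
    }
  }
  present <- total > 0
  mean(correct[present] / total[present])
}

rmsprop_step <- function(model, lr, alpha, eps) {
  if (is.null(model$opt_sq))
    model$opt_sq <- lapply(model$params, function(p) p$v * 0)
  for (i in seq_along(model$params)) {
    p <- model$params[[i]]
    if (is.null(p$g)) next
    model$opt_sq[[i]] <- alpha * model$opt_sq[[i]] + (1 - alpha) * p$g^2
    p$v <- p$v - lr * p$g / (sqrt(model$opt_sq[[i]]) + eps)
  }
  invisible(NULL)
}

#' Train the multi-task network
#'
#' Minimizes `L = L1 + L2` with RMSprop under the configured learning-rate
#' schedule, sampling minibatches with per-epoch shuffling and applying
#' flip/rotation augmentation. Validation (class-average pixel accuracy) is
#' run every `validation_interval` iterations and the best-on-validation
#' weights are restored before returning. Aborts with a diagnostic if the
#' loss becomes non-finite.
#'
#' @param model a `ra_model` (modified in place; also returned).
#' @param train_set,val_set lists of samples
#'   `list(image = (H,W,3), masks = (h,w,3), heats = (h,w,3))` with targets
#'   at half the image resolution.
#' @param config a `ra_train_config`.
#' @param verbose print progress lines.
#' @return list `(model, history, best_val, alpha)`; `history` is a data
#'   frame with iteration, lr, l1, l2, loss and validation accuracy.
#' @export
train <- function(model, train_set, val_set, config = train_config(),
                  verbose = FALSE) {
  stopifnot(length(train_set) > 0, length(val_set) > 0)
  if (config$max_iterations == 0L)
    return(list(model = model, history = NULL, best_val = NA_real_,
                alpha = NULL))
  old <- local_seed(config$rng_seed)
  on.exit(restore_seed(old))
  bal <- class_balance_weights(lapply(train_set, function(s) s$masks))
  alpha <- bal$alpha
  heat_alpha <- if (is.null(config$heat_alpha)) rep(1, 3) else config$heat_alpha
  ntr <- length(train_set)
  order_idx <- sample(ntr)
  cursor <- 0L
  hist <- vector("list", config$max_iterations)
  best_val <- -Inf
  best_state <- NULL
  for (it in seq_len(config$max_iterations) - 1L) {
    take <- integer(0)
    while (length(take) < config$batch_size) {
      if (cursor == ntr) {
        order_idx <- sample(ntr)
        cursor <- 0L
      }
      k <- min(config$batch_size - length(take), ntr - cursor)
      take <- c(take, order_idx[cursor + seq_len(k)])
      cursor <- cursor + k
    }
    aug <- lapply(train_set[take], function(s)
      augment(s$image, s$masks, s$heats, config$flip_prob,
              config$rotation_range))
    x <- stack_batch(lapply(aug, `[[`, "image"))
    g <- stack_batch(lapply(aug, `[[`, "masks"))
    p <- stack_batch(lapply(aug, `[[`, "heats"))
    B <- dim(x)[4]

    out <- model_forward(model, x, training = TRUE)
    # per-pixel balancing: every channel at a pixel is weighted by the
    # balancing weight of that pixel's true class (rare-class pixels are
    # amplified on all channels, so the background logit is suppressed at
    # root pixels at the same weighted rate the root logit is raised)
    wseg <- pixel_class_weights(g, alpha)
    lo <- ft_multitask_loss(out$seg$v, out$heat$v, g, p, wseg, heat_alpha)
    l1 <- lo$l1
    l2 <- lo$l2
    loss <- total_loss(l1, l2)
    if (!is.finite(loss))
      stop("training diverged at iteration ", it, ": loss = ", loss,
           " (l1 = ", l1, ", l2 = ", l2, ")")
    param_zero_grad(model$params)
    out$seg$g <- lo$gseg
    out$heat$g <- lo$gheat
    tape_run_backward(out$tape)
    lr <- lr_schedule(it, config)
    rmsprop_step(model, lr, config$rmsprop_alpha, config$rmsprop_eps)

    val_acc <- NA_real_
    if ((it + 1L) %% config$validation_interval == 0L ||
        it + 1L == config$max_iterations) {
      val_acc <- validate_model(model, val_set)
      if (val_acc >= best_val) {
        best_val <- val_acc
        best_state <- model_state(model)
      }
      if (verbose)
        message(sprintf("iter %d lr %.1e L1 %.4f L2 %.4f val %.3f",
                        it + 1L, lr, l1, l2, val_acc))
    }
    hist[[it + 1L]] <- data.frame(iteration = it + 1L, lr = lr, l1 = l1,
                                  l2 = l2, loss = loss, val_acc = val_acc)
    # recycle activation buffers promptly (externalptr finalizers feed the
    # C++ buffer pool only when R collects)
    if ((it + 1L) %% 5L == 0L) gc(verbose = FALSE, full = FALSE)
  }
  if (!is.null(best_state)) load_state(model, best_state)
  list(model = model, history = do.call(rbind, hist), best_val = best_val,
       alpha = alpha)
}

#' Transfer learning from an existing model
#'
#' Initializes a structurally identical network from `base_model`'s weights
#' (erroring on any layer-shape mismatch) and trains on the new dataset; the
#' iteration budget defaults to 120000. Grayscale datasets should be passed
#' through [gray_to_rgb()] so the 3-channel input layer is reused unchanged.
#'
#' @param base_model trained `ra_model` to start from.
#' @param train_set,val_set new dataset (as in [train()]).
#' @param config a `ra_train_config`; `max_iterations` is capped at 120000.
#' @return as [train()].
#' @export
transfer_learn <- function(base_model, train_set, val_set,
                           config = train_config(max_iterations = 120000L)) {
  model <- build_network(base_model$spec, rng_seed = config$rng_seed)
  load_state(model, model_state(base_model))
  if (config$max_iterations > 120000L) config$max_iterations <- 120000L
  if (config$max_iterations == 0L)
    return(list(model = model, history = NULL, best_val = NA_real_,
                alpha = NULL))
  train(model, train_set, val_set, config)
}

#' Write a training history to CSV
#'
#' @param history data frame from [train()].
#' @param path output path.
#' @export
write_history_csv <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
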