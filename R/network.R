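# The multi-task encoder-decoder. A 7x7 stride-2 stem and two
# residual-block/max-pool stages reduce a (2s x 2s) input to (s/4)^2 feature
# maps; a single (non-stacked) hourglass encodes and decodes at that scale;
# two transposed convolutions interleaved with residual blocks return to
# (s)^2, where the trunk splits into a segmentation branch (3 classes:
# background, first-order, second-order) and a heat-map regression branch
# (3 channels: seed, first-order tips, second-order tips).

#' Network specification
#'
#' Describes the multi-task root-segmentation network. The default
#' specification (`width_multiplier = 1`) is the full-size network: a 7x7/2
#' stem to 64 features, bottleneck residual blocks (expansion 4) with two
#' max-poolings to 256 features at 1/8 input resolution, a single depth-4
#' hourglass (three bottlenecks per level, max-pool down / bilinear up), a
#' 1x1 convolution stage, then a transposed-convolution decoder
#' (256 -> 256 -> 128 features) and two 1x1-convolution branches of 3
#' channels each at half the input resolution.
#'
#' `width_multiplier` scales every internal channel count (but not the 3 input
#' or 3 output channels), giving structurally identical scaled-down variants
#' for CPU-sized experiments.
#'
#' @param width_multiplier positive scalar channel-width factor (default 1).
#' @param input_channels number of image channels expected (fixed at 3;
#'   grayscale images are channel-duplicated before the forward pass).
#' @param hourglass_depth number of pooling levels inside the hourglass
#'   (default 4, i.e. 1/8 input resolution down to 1/128).
#' @return an object of class `ra_netspec`.
#' @export
network_spec <- function(width_multiplier = 1, input_channels = 3L,
                         hourglass_depth = 4L) {
  if (!is.numeric(width_multiplier) || length(width_multiplier) != 1 ||
      !is.finite(width_multiplier) || width_multiplier <= 0)
    stop("width_multiplier must be a positive scalar")
  ch <- function(base) max(1L, as.integer(round(base * width_multiplier)))
  spec <- list(
    width_multiplier = width_multiplier,
    input_channels = as.integer(input_channels),
    hourglass_depth = as.integer(hourglass_depth),
    stem = ch(64), c128 = ch(128), c256 = ch(256),
    p32 = ch(32), p64 = ch(64), n_classes = 3L, n_heat = 3L)
  class(spec) <- "ra_netspec"
  spec
}

build_hourglass <- function(ch, planes, depth) {
  levels <- lapply(seq_len(depth), function(i) {
    list(skip = layer_bottleneck(ch, planes, ch),
         down = layer_bottleneck(ch, planes, ch),
         out  = layer_bottleneck(ch, planes, ch))
  })
  hg <- new.env(parent = emptyenv())
  hg$levels <- levels
  hg$params <- do.call(c, lapply(levels, function(l)
    c(l$skip$params, l$down$params, l$out$params)))
  rec <- function(tape, x, lvl, training) {
    l <- levels[[lvl]]
    s <- l$skip$fwd(tape, x, training)
    d <- op_maxpool(tape, x)
    d <- l$down$fwd(tape, d, training)
    m <- if (lvl > 1) rec(tape, d, lvl - 1L, training) else d
    u <- op_upsample2(tape, m)
    l$out$fwd(tape, op_add(tape, s, u), training)
  }
  hg$fwd <- function(tape, x, training) rec(tape, x, depth, training)
  hg
}

#' Build the multi-task network
#'
#' Instantiates the network described by a [network_spec()]. The model is
#' fully convolutional: an input of shape `(H, W, 3, N)` (with `H`, `W`
#' divisible by `2^(3 + hourglass_depth)`) yields two outputs of shape
#' `(H/2, W/2, 3, N)`; the trainable parameter count is independent of the
#' input size.
#'
#' @param spec a `ra_netspec`, or arguments forwarded to [network_spec()].
#' @param rng_seed integer seed for weight initialisation.
#' @return an object of class `ra_model`.
#' @export
build_network <- function(spec = network_spec(), rng_seed = 1L) {
  if (!inherits(spec, "ra_netspec")) stop("spec must be a ra_netspec")
  old <- local_seed(rng_seed)
  on.exit(restore_seed(old))
  L <- list()
  L$stem <- layer_conv(7L, spec$input_channels, spec$stem, stride = 2L,
                       pad = 3L, bias = FALSE)
  L$stem_bn <- layer_bnorm(spec$stem, relu = TRUE)
  L$rb1 <- layer_bottleneck(spec$stem, spec$p32, spec$c128)
  L$rb2 <- layer_bottleneck(spec$c128, spec$p32, spec$c128)
  L$rb3 <- layer_bottleneck(spec$c128, spec$p64, spec$c256)
  L$hg <- build_hourglass(spec$c256, spec$p64, spec$hourglass_depth)
  L$fc1 <- layer_conv(1L, spec$c256, spec$c256, bias = TRUE)
  L$fc1_bn <- layer_bnorm(spec$c256, relu = TRUE)
  L$up1 <- layer_convt(2L, spec$c256, spec$c256, bias = FALSE)
  L$up1_bn <- layer_bnorm(spec$c256, relu = TRUE)
  L$rb4 <- layer_bottleneck(spec$c256, spec$p64, spec$c256)
  L$up2 <- layer_convt(2L, spec$c256, spec$c128, bias = FALSE)
  L$up2_bn <- layer_bnorm(spec$c128, relu = TRUE)
  L$rb5 <- layer_bottleneck(spec$c128, spec$p32, spec$c128)
  L$fc2 <- layer_conv(1L, spec$c128, spec$c128, bias = TRUE)
  L$seg_a <- layer_conv(1L, spec$c128, spec$c128, bias = TRUE)
  L$seg_b <- layer_conv(1L, spec$c128, spec$n_classes, bias = TRUE)
  L$heat_a <- layer_conv(1L, spec$c128, spec$c128, bias = TRUE)
  L$heat_b <- layer_conv(1L, spec$c128, spec$n_heat, bias = TRUE)

  model <- new.env(parent = emptyenv())
  model$spec <- spec
  model$layers <- L
  model$params <- do.call(c, lapply(L, function(x) x$params))
  model$bnorms <- Filter(function(x) identical(x$type, "bnorm"),
                         unlist(lapply(L, function(x) {
                           if (identical(x$type, "bottleneck"))
                             list(x$bn1, x$bn2, x$bn3)
                           else if (!is.null(x$levels))
                             unlist(lapply(x$levels, function(l)
                               lapply(list(l$skip, l$down, l$out), function(b)
                                 list(b$bn1, b$bn2, b$bn3))), recursive = TRUE)
                           else list(x)
                         }), recursive = TRUE))
  class(model) <- "ra_model"
  model
}

# Forward pass recording a tape. Returns nodes for the segmentation logits
# and heat-map outputs. Spatial dims must be divisible by 2^(3 + depth).
model_forward <- function(model, x, training = FALSE, tape = NULL) {
  L <- model$layers
  need <- 2^(3L + model$spec$hourglass_depth)
  d <- dim(x)
  if (length(d) != 4L) stop("input must be (H, W, C, N)")
  if (d[1] %% need != 0 || d[2] %% need != 0)
    stop("input side lengths must be divisible by ", need)
  if (d[3] != model$spec$input_channels)
    stop("expected ", model$spec$input_channels, " input channels")
  if (is.null(tape)) tape <- new_tape()
  h <- tape_node(tape, ft_from_array(x))
  h <- L$stem$fwd(tape, h, training)
  h <- L$stem_bn$fwd(tape, h, training)
  h <- L$rb1$fwd(tape, h, training)
  h <- op_maxpool(tape, h)
  h <- L$rb2$fwd(tape, h, training)
  h <- op_maxpool(tape, h)
  h <- L$rb3$fwd(tape, h, training)
  h <- L$hg$fwd(tape, h, training)
  h <- L$fc1$fwd(tape, h, training)
  h <- L$fc1_bn$fwd(tape, h, training)
  h <- L$up1$fwd(tape, h, training)
  h <- L$up1_bn$fwd(tape, h, training)
  h <- L$rb4$fwd(tape, h, training)
  h <- L$up2$fwd(tape, h, training)
  h <- L$up2_bn$fwd(tape, h, training)
  h <- L$rb5$fwd(tape, h, training)
  h <- L$fc2$fwd(tape, h, training)
  h <- op_relu(tape, h)
  s <- L$seg_a$fwd(tape, h, training)
  s <- op_relu(tape, s)
  seg <- L$seg_b$fwd(tape, s, training)
  p <- L$heat_a$fwd(tape, h, training)
  p <- op_relu(tape, p)
  heat <- L$heat_b$fwd(tape, p, training)
  if (training)
    list(seg = seg, heat = heat, tape = tape)
  else
    list(seg = seg, heat = heat, tape = tape,
         seg_array = ft_to_array(seg$v), heat_array = ft_to_array(heat$v))
}

softmax_channels <- function(x) {
  # x: (H, W, C, N); softmax across C
  m <- apply(x, c(1, 2, 4), max)
  d <- dim(x)
  e <- exp(x - aperm(array(m, dim = c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3)))
  s <- apply(e, c(1, 2, 4), sum)
  e / aperm(array(s, dim = c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

#' Run inference on a batch of images
#'
#' Forward pass in evaluation mode. The segmentation branch is returned both
#' as per-channel sigmoid activations (the form the loss is trained on) and
#' softmax-normalised class probabilities (the form post-processing uses);
#' heat maps are clamped to `[0, 1]`.
#'
#' @param model a `ra_model`.
#' @param x numeric array `(H, W, 3, N)` in `[0, 1]`, or `(H, W, 3)` for a
#'   single image.
#' @return list with `seg_prob` (softmax), `seg_sigmoid`, `heat`.
#' @export
net_predict <- function(model, x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  out <- model_forward(model, x, training = FALSE)
  seg <- out$seg_array
  heat <- pmin(pmax(out$heat_array, 0), 1)
  list(seg_prob = softmax_channels(seg),
       seg_sigmoid = 1 / (1 + exp(-seg)),
       heat = heat)
}

#' Count trainable parameters
#'
#' Counts every independently trainable scalar weight in the model:
#' convolution and transposed-convolution kernels and biases, and the
#' learnable affine terms of every batch-normalization layer. Running
#' statistics are not trainable and are excluded.
#'
#' @param model a `ra_model`.
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, function(p) length(p$v), numeric(1)))
}

#' Save / load model checkpoints
#'
#' A checkpoint stores the network spec, all trainable parameters and the
#' batch-normalization running statistics. Loading rebuilds the network from
#' the embedded spec (or loads into an existing structurally identical
#' model, erroring on any shape mismatch).
#'
#' @param model a `ra_model`.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  state <- list(spec = model$spec,
                params = lapply(model$params, function(p) p$v),
                rstats = lapply(model$bnorms, function(b)
                  list(rmean = b$rmean, rvar = b$rvar)))
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param into optional existing `ra_model` to load the weights into.
#' @export
load_checkpoint <- function(path, into = NULL) {
  state <- readRDS(path)
  model <- if (is.null(into)) build_network(state$spec) else into
  load_state(model, state)
  model
}

load_state <- function(model, state) {
  if (length(model$params) != length(state$params))
    stop("checkpoint load error: parameter list length mismatch")
  for (i in seq_along(model$params)) {
    v <- state$params[[i]]
    tgt <- model$params[[i]]$v
    if (!identical(dim(v), dim(tgt)) || length(v) != length(tgt))
      stop("checkpoint load error: shape mismatch at parameter ", i)
    model$params[[i]]$v <- v
  }
  if (length(model$bnorms) == length(state$rstats)) {
    for (i in seq_along(model$bnorms)) {
      model$bnorms[[i]]$rmean <- state$rstats[[i]]$rmean
      model$bnorms[[i]]$rvar <- state$rstats[[i]]$rvar
    }
  }
  invisible(model)
}

# Deep-copy the trainable state of a model (for best-checkpoint selection).
model_state <- function(model) {
  list(spec = model$spec,
       params = lapply(model$params, function(p) p$v),
       rstats = lapply(model$bnorms, function(b)
         list(rmean = b$rmean, rvar = b$rvar)))
}
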