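# Layer constructors for the segmentation/localization network. Each layer is
# an environment holding its parameters (ra_param) plus a fwd(tape, x_node,
# training) method that records the op and its backward rule on the tape.

he_init <- function(k, cin, cout, rng) {
  sd <- sqrt(2 / (k * k * cin))
  array(stats::rnorm(k * k * cin * cout, 0, sd) , dim = c(k, k, cin, cout))
}

layer_conv <- function(k, cin, cout, stride = 1L, pad = (k - 1L) %/% 2L,
                       bias = TRUE) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "conv"
  ly$k <- k; ly$stride <- as.integer(stride); ly$pad <- as.integer(pad)
  ly$W <- new_param(he_init(k, cin, cout))
  ly$b <- if (bias) new_param(numeric(cout)) else NULL
  ly$params <- if (bias) list(ly$W, ly$b) else list(ly$W)
  ly$fwd <- function(tape, x, training) {
    b <- if (is.null(ly$b)) numeric(0) else ly$b$v
    y <- ft_conv2d_fwd(x$v, ly$W$v, b, ly$stride, ly$pad)
    tape_node(tape, y, backward = function(g) {
      gr <- ft_conv2d_bwd(x$v, ly$W$v, g, ly$stride, ly$pad, !is.null(ly$b))
      param_accum(ly$W, gr$dw)
      if (!is.null(ly$b)) param_accum(ly$b, gr$db)
      node_accum(x, gr$dx)
    })
  }
  ly
}

# Transposed convolution with kernel == stride (block upsampling).
layer_convt <- function(k, cin, cout, bias = FALSE) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "convt"
  ly$k <- as.integer(k)
  ly$W <- new_param(he_init(k, cin, cout))
  ly$b <- if (bias) new_param(numeric(cout)) else NULL
  ly$params <- if (bias) list(ly$W, ly$b) else list(ly$W)
  ly$fwd <- function(tape, x, training) {
    b <- if (is.null(ly$b)) numeric(0) else ly$b$v
    y <- ft_convt_fwd(x$v, ly$W$v, b, ly$k)
    tape_node(tape, y, backward = function(g) {
      gr <- ft_convt_bwd(x$v, ly$W$v, g, ly$k, !is.null(ly$b))
      param_accum(ly$W, gr$dw)
      if (!is.null(ly$b)) param_accum(ly$b, gr$db)
      node_accum(x, gr$dx)
    })
  }
  ly
}

# Batch normalization; with relu = TRUE the activation is fused into the
# same pass (both directions), halving memory traffic.
layer_bnorm <- function(c, momentum = 0.1, eps = 1e-5, relu = FALSE) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "bnorm"
  ly$relu <- relu
  ly$gamma <- new_param(rep(1, c))
  ly$beta <- new_param(numeric(c))
  ly$rmean <- numeric(c)
  ly$rvar <- rep(1, c)
  ly$momentum <- momentum; ly$eps <- eps
  ly$params <- list(ly$gamma, ly$beta)
  ly$fwd <- function(tape, x, training) {
    r <- ft_bnorm_fwd(x$v, ly$gamma$v, ly$beta$v, ly$rmean, ly$rvar,
                      training, ly$momentum, ly$eps, ly$relu)
    if (training) {
      ly$rmean <- r$rmean
      ly$rvar <- r$rvar
    }
    tape_node(tape, r$y, backward = function(g) {
      gr <- ft_bnorm_bwd(x$v, ly$gamma$v, ly$beta$v, r$mean, r$invstd, g,
                         ly$relu)
      param_accum(ly$gamma, gr$dgamma)
      param_accum(ly$beta, gr$dbeta)
      node_accum(x, gr$dx)
    })
  }
  ly
}

op_relu <- function(tape, x) {
  y <- ft_relu_fwd(x$v)
  tape_node(tape, y, backward = function(g) {
    node_accum(x, ft_relu_bwd(x$v, g))
  })
}

op_maxpool <- function(tape, x) {
  r <- ft_maxpool_fwd(x$v)
  xd <- ft_dims(x$v)
  tape_node(tape, r$y, backward = function(g) {
    node_accum(x, ft_maxpool_bwd(g, r$argmax, xd))
  })
}

op_upsample2 <- function(tape, x) {
  d <- ft_dims(x$v)
  y <- ft_resize_bilinear(x$v, 2L * d[1], 2L * d[2])
  tape_node(tape, y, backward = function(g) {
    node_accum(x, ft_resize_bilinear_bwd(g, d[1], d[2]))
  })
}

op_add <- function(tape, a, b) {
  tape_node(tape, ft_add(a$v, b$v), backward = function(g) {
    node_accum(a, g)
    node_accum(b, g)
  })
}

# Pre-activation bottleneck residual block: BN-ReLU-1x1(reduce) ->
# BN-ReLU-3x3 -> BN-ReLU-1x1(expand), identity skip (1x1 projection on
# channel change).
layer_bottleneck <- function(cin, planes, cout) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "bottleneck"
  ly$bn1 <- layer_bnorm(cin, relu = TRUE)
  ly$c1 <- layer_conv(1L, cin, planes, bias = TRUE)
  ly$bn2 <- layer_bnorm(planes, relu = TRUE)
  ly$c2 <- layer_conv(3L, planes, planes, bias = TRUE)
  ly$bn3 <- layer_bnorm(planes, relu = TRUE)
  ly$c3 <- layer_conv(1L, planes, cout, bias = TRUE)
  ly$down <- if (cin != cout) layer_conv(1L, cin, cout, bias = TRUE) else NULL
  subs <- list(ly$bn1, ly$c1, ly$bn2, ly$c2, ly$bn3, ly$c3)
  if (!is.null(ly$down)) subs <- c(subs, list(ly$down))
  ly$params <- do.call(c, lapply(subs, function(s) s$params))
  ly$fwd <- function(tape, x, training) {
    h <- ly$bn1$fwd(tape, x, training)
    h <- ly$c1$fwd(tape, h, training)
    h <- ly$bn2$fwd(tape, h, training)
    h <- ly$c2$fwd(tape, h, training)
    h <- ly$bn3$fwd(tape, h, training)
    h <- ly$c3$fwd(tape, h, training)
    skip <- if (is.null(ly$down)) x else ly$down$fwd(tape, x, training)
    op_add(tape, h, skip)
  }
  ly
}
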