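# Minimal reverse-mode tape for array-valued operations. Each forward pass
# through the network records nodes on a fresh tape; backward() replays it in
# reverse. Parameters live outside the tape and accumulate gradients in-place
# (in their own environments) across a pass.

new_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$v <- value
  p$g <- NULL
  class(p) <- "ra_param"
  p
}

param_zero_grad <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}

# Gradient buffers are adopted by reference on first write (the source may
# be shared, e.g. both parents of an add receive the same array), copied on
# the second write, and accumulated in place thereafter.
param_accum <- function(p, g) {
  if (is.null(p$g)) {
    p$g <- g
    p$g_owned <- FALSE
  } else if (!isTRUE(p$g_owned)) {
    p$g <- p$g + g
    p$g_owned <- TRUE
  } else {
    cpp_axpy_inplace(p$g, g)
  }
  invisible(NULL)
}

new_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

tape_node <- function(tape, value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$v <- value
  nd$g <- NULL
  nd$backward <- backward
  if (!is.null(tape)) {
    if (tape$n == length(tape$nodes))
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    tape$n <- tape$n + 1L
    tape$nodes[[tape$n]] <- nd
  }
  nd
}

# Node values and gradients are single-precision C++ tensors (externalptr).
node_accum <- function(nd, g) {
  if (is.null(nd$g)) {
    nd$g <- g
    nd$g_owned <- FALSE
  } else if (!isTRUE(nd$g_owned)) {
    nd$g <- ft_add(nd$g, g)
    nd$g_owned <- TRUE
  } else {
    ft_axpy_inplace(nd$g, g)
  }
  invisible(NULL)
}

# Replay the tape backwards, assuming output-node gradients have been
# seeded. Parameter gradients accumulate in their environments.
tape_run_backward <- function(tape) {
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$g) && !is.null(nd$backward)) nd$backward(nd$g)
    nd$backward <- NULL  # release closures promptly
    nd$g <- NULL
  }
  invisible(NULL)
}

# Seed a single root node with an R-array gradient and run the tape
# backwards.
tape_backward <- function(tape, root, seed) {
  root$g <- ft_from_array(seed)
  tape_run_backward(tape)
}
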