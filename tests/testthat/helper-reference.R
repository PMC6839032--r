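# Naive double-precision reference implementation of the network's forward
# pass, independent of the package's im2col/GEMM kernels. Used as an oracle
# on tiny inputs.

ref_conv <- function(x, w, b, stride = 1, pad = (dim(w)[1] - 1) %/% 2) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]; N <- dim(x)[4]
  k <- dim(w)[1]; Cout <- dim(w)[4]
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (W + 2 * pad - k) %/% stride + 1
  xp <- array(0, dim = c(H + 2 * pad, W + 2 * pad, C, N))
  xp[pad + seq_len(H), pad + seq_len(W), , ] <- x
  y <- array(0, dim = c(Ho, Wo, Cout, N))
  for (n in seq_len(N))
    for (co in seq_len(Cout))
      for (j in seq_len(Wo))
        for (i in seq_len(Ho)) {
          patch <- xp[(i - 1) * stride + seq_len(k),
                      (j - 1) * stride + seq_len(k), , n]
          y[i, j, co, n] <- sum(patch * w[, , , co]) +
            (if (length(b)) b[co] else 0)
        }
  y
}

ref_convt <- function(x, w, b, stride) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]; N <- dim(x)[4]
  k <- dim(w)[1]; Cout <- dim(w)[4]
  y <- array(0, dim = c(H * stride, W * stride, Cout, N))
  for (n in seq_len(N))
    for (co in seq_len(Cout))
      for (j in seq_len(W))
        for (i in seq_len(H))
          for (kw in seq_len(k))
            for (kh in seq_len(k))
              y[(i - 1) * stride + kh, (j - 1) * stride + kw, co, n] <-
                sum(x[i, j, , n] * w[kh, kw, , co]) +
                (if (length(b)) b[co] else 0)
  y
}

ref_bn <- function(x, gamma, beta, eps = 1e-5, relu = FALSE) {
  y <- x
  for (c in seq_len(dim(x)[3])) {
    v <- x[, , c, , drop = FALSE]
    mu <- mean(v)
    s2 <- mean((v - mu)^2)
    y[, , c, ] <- gamma[c] * (v - mu) / sqrt(s2 + eps) + beta[c]
  }
  if (relu) y[y < 0] <- 0
  y
}

ref_pool <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]
  y <- array(0, dim = c(H / 2, W / 2, dim(x)[3], dim(x)[4]))
  for (i in seq_len(H / 2))
    for (j in seq_len(W / 2))
      y[i, j, , ] <- pmax(x[2 * i - 1, 2 * j - 1, , ], x[2 * i, 2 * j - 1, , ],
                          x[2 * i - 1, 2 * j, , ], x[2 * i, 2 * j, , ])
  y
}

ref_upsample2 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]
  Ho <- 2 * H; Wo <- 2 * W
  cf <- function(Ho, H) {
    s <- (seq_len(Ho) - 0.5) * H / Ho - 0.5
    s <- pmin(pmax(s, 0), H - 1)
    list(i0 = floor(s) + 1, i1 = pmin(floor(s) + 2, H), f = s - floor(s))
  }
  a <- cf(Ho, H); b <- cf(Wo, W)
  y <- array(0, dim = c(Ho, Wo, dim(x)[3], dim(x)[4]))
  for (i in seq_len(Ho))
    for (j in seq_len(Wo)) {
      top <- x[a$i0[i], b$i0[j], , ] * (1 - a$f[i]) + x[a$i1[i], b$i0[j], , ] * a$f[i]
      bot <- x[a$i0[i], b$i1[j], , ] * (1 - a$f[i]) + x[a$i1[i], b$i1[j], , ] * a$f[i]
      y[i, j, , ] <- top * (1 - b$f[j]) + bot * b$f[j]
    }
  y
}

ref_bottleneck <- function(x, blk) {
  h <- ref_bn(x, blk$bn1$gamma$v, blk$bn1$beta$v, relu = TRUE)
  h <- ref_conv(h, blk$c1$W$v, blk$c1$b$v)
  h <- ref_bn(h, blk$bn2$gamma$v, blk$bn2$beta$v, relu = TRUE)
  h <- ref_conv(h, blk$c2$W$v, blk$c2$b$v)
  h <- ref_bn(h, blk$bn3$gamma$v, blk$bn3$beta$v, relu = TRUE)
  h <- ref_conv(h, blk$c3$W$v, blk$c3$b$v)
  skip <- if (is.null(blk$down)) x else ref_conv(x, blk$down$W$v, blk$down$b$v)
  h + skip
}

ref_hourglass <- function(x, hg, lvl) {
  l <- hg$levels[[lvl]]
  s <- ref_bottleneck(x, l$skip)
  d <- ref_bottleneck(ref_pool(x), l$down)
  m <- if (lvl > 1) ref_hourglass(d, hg, lvl - 1) else d
  ref_bottleneck(s + ref_upsample2(m), l$out)
}

ref_relu <- function(x) { x[x < 0] <- 0; x }

# Full forward pass (training-mode batch statistics), double precision.
ref_forward <- function(model, x) {
  L <- model$layers
  h <- ref_conv(x, L$stem$W$v, numeric(0), stride = 2, pad = 3)
  h <- ref_bn(h, L$stem_bn$gamma$v, L$stem_bn$beta$v, relu = TRUE)
  h <- ref_bottleneck(h, L$rb1)
  h <- ref_pool(h)
  h <- ref_bottleneck(h, L$rb2)
  h <- ref_pool(h)
  h <- ref_bottleneck(h, L$rb3)
  h <- ref_hourglass(h, L$hg, model$spec$hourglass_depth)
  h <- ref_conv(h, L$fc1$W$v, L$fc1$b$v)
  h <- ref_bn(h, L$fc1_bn$gamma$v, L$fc1_bn$beta$v, relu = TRUE)
  h <- ref_convt(h, L$up1$W$v, numeric(0), 2)
  h <- ref_bn(h, L$up1_bn$gamma$v, L$up1_bn$beta$v, relu = TRUE)
  h <- ref_bottleneck(h, L$rb4)
  h <- ref_convt(h, L$up2$W$v, numeric(0), 2)
  h <- ref_bn(h, L$up2_bn$gamma$v, L$up2_bn$beta$v, relu = TRUE)
  h <- ref_bottleneck(h, L$rb5)
  h <- ref_relu(ref_conv(h, L$fc2$W$v, L$fc2$b$v))
  s <- ref_relu(ref_conv(h, L$seg_a$W$v, L$seg_a$b$v))
  seg <- ref_conv(s, L$seg_b$W$v, L$seg_b$b$v)
  p <- ref_relu(ref_conv(h, L$heat_a$W$v, L$heat_a$b$v))
  heat <- ref_conv(p, L$heat_b$W$v, L$heat_b$b$v)
  list(seg = seg, heat = heat)
}
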