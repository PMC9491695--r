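# Compact convolutional network engine.
#
# Layers are mutable environments holding parameters, Adam moments and
# per-sample caches. The engine provides exactly what the conditional GAN
# needs: 2-D convolutions (C++ im2col + GEMM), instance normalization,
# leaky-ReLU/ReLU/tanh/sigmoid activations, nearest-neighbour upsampling,
# channel concatenation, and an Adam optimizer with linear learning-rate
# decay. Everything is single-sample (batch size one).

nn_conv <- function(cin, cout, k = 3L, stride = 1L, pad = 1L,
                    init_sd = 0.02) {
  e <- new.env(parent = emptyenv())
  e$type <- "conv"
  e$k <- as.integer(k); e$stride <- as.integer(stride)
  e$pad <- as.integer(pad)
  e$W <- matrix(rnorm(k * k * cin * cout, sd = init_sd), k * k * cin, cout)
  e$b <- numeric(cout)
  e$mW <- e$W * 0; e$vW <- e$W * 0
  e$mb <- e$b * 0; e$vb <- e$b * 0
  e
}

conv_forward <- function(e, x) {
  res <- cpp_conv_forward(x, e$W, e$b, e$k, e$stride, e$pad)
  e$cols <- res$cols
  e$xdim <- dim(x)
  res$out
}

conv_backward <- function(e, dout) {
  res <- cpp_conv_backward(e$cols, e$W, dout, e$xdim, e$k, e$stride, e$pad)
  e$dW <- res$dW
  e$db <- res$db
  res$dx
}

nn_instnorm <- function(c, eps = 1e-5) {
  e <- new.env(parent = emptyenv())
  e$type <- "instnorm"
  e$gamma <- rep(1, c); e$beta <- numeric(c)
  e$eps <- eps
  e$mW <- e$gamma * 0; e$vW <- e$gamma * 0
  e$mb <- e$beta * 0; e$vb <- e$beta * 0
  e
}

instnorm_forward <- function(e, x) {
  d <- dim(x); n <- d[1] * d[2]
  X <- matrix(x, n, d[3])
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  v <- colSums(Xc^2) / n
  istd <- 1 / sqrt(v + e$eps)
  xhat <- sweep(Xc, 2L, istd, `*`)
  e$xhat <- xhat; e$istd <- istd; e$dims <- d
  out <- sweep(sweep(xhat, 2L, e$gamma, `*`), 2L, e$beta, `+`)
  array(out, d)
}

instnorm_backward <- function(e, dout) {
  d <- e$dims; n <- d[1] * d[2]
  Do <- matrix(dout, n, d[3])
  e$dW <- colSums(Do * e$xhat)  # dgamma
  e$db <- colSums(Do)           # dbeta
  dxhat <- sweep(Do, 2L, e$gamma, `*`)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * e$xhat)
  dx <- sweep(dxhat, 2L, s1 / n) - sweep(e$xhat, 2L, s2 / n, `*`)
  dx <- sweep(dx, 2L, e$istd, `*`)
  array(dx, d)
}

nn_act <- function(kind) {
  e <- new.env(parent = emptyenv())
  e$type <- "act"; e$kind <- kind
  e
}

act_forward <- function(e, x) {
  out <- switch(e$kind,
    lrelu = ifelse(x > 0, x, 0.2 * x),
    relu = pmax(x, 0),
    tanh = tanh(x),
    sigmoid = 1 / (1 + exp(-x)))
  if (is.null(dim(out))) dim(out) <- dim(x)
  e$x <- x; e$out <- out
  out
}

act_backward <- function(e, dout) {
  g <- switch(e$kind,
    lrelu = ifelse(e$x > 0, 1, 0.2),
    relu = (e$x > 0) * 1,
    tanh = 1 - e$out^2,
    sigmoid = e$out * (1 - e$out))
  out <- dout * g
  if (is.null(dim(out))) dim(out) <- dim(dout)
  out
}

# nearest-neighbour x2 upsampling; backward sums each 2x2 block
upsample2_forward <- function(x) {
  d <- dim(x)
  idx_r <- rep(seq_len(d[1]), each = 2L)
  idx_c <- rep(seq_len(d[2]), each = 2L)
  x[idx_r, idx_c, , drop = FALSE]
}

upsample2_backward <- function(dout) {
  d <- dim(dout)
  H <- d[1] %/% 2L; W <- d[2] %/% 2L
  out <- array(0, c(H, W, d[3]))
  out <- dout[seq(1, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
    dout[seq(2, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
    dout[seq(1, d[1], 2), seq(2, d[2], 2), , drop = FALSE] +
    dout[seq(2, d[1], 2), seq(2, d[2], 2), , drop = FALSE]
  out
}

# ---- Adam ----------------------------------------------------------------

adam_step <- function(layers, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      t = 1L) {
  corr <- sqrt(1 - beta2^t) / (1 - beta1^t)
  for (e in layers) {
    if (is.null(e$dW)) next
    e$mW <- beta1 * e$mW + (1 - beta1) * e$dW
    e$vW <- beta2 * e$vW + (1 - beta2) * e$dW^2
    e$mb <- beta1 * e$mb + (1 - beta1) * e$db
    e$vb <- beta2 * e$vb + (1 - beta2) * e$db^2
    if (e$type == "conv") {
      e$W <- e$W - lr * corr * e$mW / (sqrt(e$vW) + eps)
      e$b <- e$b - lr * corr * e$mb / (sqrt(e$vb) + eps)
    } else {
      e$gamma <- e$gamma - lr * corr * e$mW / (sqrt(e$vW) + eps)
      e$beta <- e$beta - lr * corr * e$mb / (sqrt(e$vb) + eps)
    }
  }
  invisible(NULL)
}

trainable_layers <- function(net) {
  Filter(function(e) e$type %in% c("conv", "instnorm"), net$layers)
}

# ---- U-Net generator -----------------------------------------------------

# Encoder: `depth` stride-2 conv blocks; decoder mirrors with
# nearest-neighbour upsampling, a 3x3 conv, and skip concatenation; a final
# 3x3 conv + tanh maps back to `cout` channels in [-1, 1].
build_generator <- function(cin, cout, depth = 3L, base_width = 16L) {
  widths <- pmin(base_width * 2^(seq_len(depth) - 1L), 8L * base_width)
  enc <- list(); layers <- list()
  prev <- cin
  for (i in seq_len(depth)) {
    blk <- list(conv = nn_conv(prev, widths[i], k = 4L, stride = 2L,
                               pad = 1L),
                norm = if (i > 1L) nn_instnorm(widths[i]),
                act = nn_act("lrelu"))
    enc[[i]] <- blk
    layers <- c(layers, blk[!vapply(blk, is.null, logical(1))])
    prev <- widths[i]
  }
  dec <- list()
  for (i in rev(seq_len(depth - 1L))) {
    blk <- list(up_conv = nn_conv(prev, widths[i], k = 3L, stride = 1L,
                                  pad = 1L),
                up_norm = nn_instnorm(widths[i]),
                up_act = nn_act("relu"),
                fuse_conv = nn_conv(2L * widths[i], widths[i], k = 3L,
                                    stride = 1L, pad = 1L),
                fuse_norm = nn_instnorm(widths[i]),
                fuse_act = nn_act("relu"))
    dec[[length(dec) + 1L]] <- blk
    layers <- c(layers, blk)
    prev <- widths[i]
  }
  head <- list(up_conv = nn_conv(prev, base_width, k = 3L, stride = 1L,
                                 pad = 1L),
               up_act = nn_act("relu"),
               out_conv = nn_conv(base_width, cout, k = 3L, stride = 1L,
                                  pad = 1L),
               out_act = nn_act("tanh"))
  layers <- c(layers, head)
  list(kind = "generator", depth = depth, enc = enc, dec = dec, head = head,
       layers = layers, cin = cin, cout = cout)
}

generator_forward <- function(net, x) {
  skips <- list()
  h <- x
  for (i in seq_len(net$depth)) {
    blk <- net$enc[[i]]
    h <- conv_forward(blk$conv, h)
    if (!is.null(blk$norm)) h <- instnorm_forward(blk$norm, h)
    h <- act_forward(blk$act, h)
    skips[[i]] <- h
  }
  for (j in seq_along(net$dec)) {
    blk <- net$dec[[j]]
    i <- net$depth - j  # encoder level being fused
    h <- upsample2_forward(h)
    h <- conv_forward(blk$up_conv, h)
    h <- instnorm_forward(blk$up_norm, h)
    h <- act_forward(blk$up_act, h)
    cat_in <- array(c(h, skips[[i]]), c(dim(h)[1:2], dim(h)[3] * 2L))
    blk$split <- dim(h)[3]
    h <- conv_forward(blk$fuse_conv, cat_in)
    h <- instnorm_forward(blk$fuse_norm, h)
    h <- act_forward(blk$fuse_act, h)
  }
  hd <- net$head
  h <- upsample2_forward(h)
  h <- conv_forward(hd$up_conv, h)
  h <- act_forward(hd$up_act, h)
  h <- conv_forward(hd$out_conv, h)
  act_forward(hd$out_act, h)
}

generator_backward <- function(net, dout) {
  hd <- net$head
  d <- act_backward(hd$out_act, dout)
  d <- conv_backward(hd$out_conv, d)
  d <- act_backward(hd$up_act, d)
  d <- conv_backward(hd$up_conv, d)
  d <- upsample2_backward(d)
  skip_grads <- vector("list", net$depth)
  for (j in rev(seq_along(net$dec))) {
    blk <- net$dec[[j]]
    i <- net$depth - j
    d <- act_backward(blk$fuse_act, d)
    d <- instnorm_backward(blk$fuse_norm, d)
    d <- conv_backward(blk$fuse_conv, d)
    split <- dim(d)[3] %/% 2L
    d_h <- d[, , seq_len(split), drop = FALSE]
    skip_grads[[i]] <- d[, , split + seq_len(split), drop = FALSE]
    d <- act_backward(blk$up_act, d_h)
    d <- instnorm_backward(blk$up_norm, d)
    d <- conv_backward(blk$up_conv, d)
    d <- upsample2_backward(d)
  }
  for (i in rev(seq_len(net$depth))) {
    blk <- net$enc[[i]]
    if (!is.null(skip_grads[[i]])) d <- d + skip_grads[[i]]
    d <- act_backward(blk$act, d)
    if (!is.null(blk$norm)) d <- instnorm_backward(blk$norm, d)
    d <- conv_backward(blk$conv, d)
  }
  d
}

# ---- Patch discriminator -------------------------------------------------

# Three convolutional blocks over the concatenated (x, y) pair; the last
# 4x4 conv maps to a grid of per-patch real/fake probabilities.
build_discriminator <- function(cin, base_width = 16L) {
  b1 <- list(conv = nn_conv(cin, base_width, k = 4L, stride = 2L, pad = 1L),
             act = nn_act("lrelu"))
  b2 <- list(conv = nn_conv(base_width, 2L * base_width, k = 4L,
                            stride = 2L, pad = 1L),
             norm = nn_instnorm(2L * base_width),
             act = nn_act("lrelu"))
  b3 <- list(conv = nn_conv(2L * base_width, 1L, k = 4L, stride = 1L,
                            pad = 1L),
             act = nn_act("sigmoid"))
  layers <- c(b1, b2[!vapply(b2, is.null, logical(1))], b3)
  list(kind = "discriminator", blocks = list(b1, b2, b3), layers = layers,
       cin = cin)
}

discriminator_forward <- function(net, xy) {
  b <- net$blocks
  h <- act_forward(b[[1]]$act, conv_forward(b[[1]]$conv, xy))
  h <- conv_forward(b[[2]]$conv, h)
  h <- instnorm_forward(b[[2]]$norm, h)
  h <- act_forward(b[[2]]$act, h)
  act_forward(b[[3]]$act, conv_forward(b[[3]]$conv, h))
}

discriminator_backward <- function(net, dout) {
  b <- net$blocks
  d <- act_backward(b[[3]]$act, dout)
  d <- conv_backward(b[[3]]$conv, d)
  d <- act_backward(b[[2]]$act, d)
  d <- instnorm_backward(b[[2]]$norm, d)
  d <- conv_backward(b[[2]]$conv, d)
  d <- act_backward(b[[1]]$act, d)
  conv_backward(b[[1]]$conv, d)
}

# snapshot / restore of all parameters (used for serialization and
# zero-epoch determinism)
net_state <- function(net) {
  lapply(net$layers, function(e) {
    if (e$type == "conv") list(type = "conv", W = e$W, b = e$b)
    else if (e$type == "instnorm") list(type = "instnorm", gamma = e$gamma,
                                        beta = e$beta)
    else list(type = e$type)
  })
}

net_restore <- function(net, state) {
  for (i in seq_along(net$layers)) {
    e <- net$layers[[i]]; s <- state[[i]]
    if (e$type == "conv") { e$W <- s$W; e$b <- s$b }
    if (e$type == "instnorm") { e$gamma <- s$gamma; e$beta <- s$beta }
  }
  invisible(net)
}

# ---- global SSIM and its gradient on [0, 1] images -----------------------

ssim_grad_channel <- function(x, y, c1, c2) {
  n <- length(x)
  mu_x <- mean(x); mu_y <- mean(y)
  xc <- x - mu_x; yc <- y - mu_y
  var_x <- sum(xc^2) / n; var_y <- sum(yc^2) / n
  cov_xy <- sum(xc * yc) / n
  A1 <- 2 * mu_x * mu_y + c1; A2 <- 2 * cov_xy + c2
  B1 <- mu_x^2 + mu_y^2 + c1; B2 <- var_x + var_y + c2
  S <- (A1 * A2) / (B1 * B2)
  grad <- (2 / n) * ((mu_y * A2 + A1 * yc) / (B1 * B2) -
                       S * (mu_x / B1 + xc / B2))
  list(value = S, grad = grad)
}
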