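# Minimal dense/conv layer kernels with explicit forward and backward passes.
# Feature maps are H x W x C arrays; convolution is im2col + BLAS matmul.
# Everything here is internal plumbing for the tiny backbone and heads.

pad_array <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  out
}

# (Ho*Wo) x (kh*kw*Cin) patch matrix; rows enumerate output positions in
# column-major order, columns enumerate (di, dj, ci) with di fastest — the
# same order as matrix(w, kh*kw*Cin, Cout).
im2col <- function(x, kh, kw, stride) {
  d <- dim(x); Cin <- d[3]
  Ho <- (d[1] - kh) %/% stride + 1L
  Wo <- (d[2] - kw) %/% stride + 1L
  i0 <- seq.int(1L, by = stride, length.out = Ho)
  j0 <- seq.int(1L, by = stride, length.out = Wo)
  cols <- matrix(0, Ho * Wo, kh * kw * Cin)
  col <- 1L
  for (ci in seq_len(Cin)) for (dj in 0:(kw - 1L)) for (di in 0:(kh - 1L)) {
    cols[, col] <- as.vector(x[i0 + di, j0 + dj, ci])
    col <- col + 1L
  }
  cols
}

conv2d_fwd <- function(x, w, b, stride = 1L, pad = 0L) {
  kh <- dim(w)[1]; kw <- dim(w)[2]; Cout <- dim(w)[4]
  xp <- pad_array(x, pad)
  d <- dim(xp)
  Ho <- (d[1] - kh) %/% stride + 1L
  Wo <- (d[2] - kw) %/% stride + 1L
  cols <- im2col(xp, kh, kw, stride)
  out <- cols %*% matrix(w, kh * kw * dim(x)[3], Cout)
  out <- sweep(out, 2L, b, "+")
  list(out = array(out, c(Ho, Wo, Cout)),
       cache = list(cols = cols, x_dim = dim(x), stride = stride, pad = pad))
}

conv2d_bwd <- function(grad_out, w, cache) {
  kh <- dim(w)[1]; kw <- dim(w)[2]; Cin <- dim(w)[3]; Cout <- dim(w)[4]
  go <- dim(grad_out)
  gm <- matrix(grad_out, go[1] * go[2], Cout)
  dW <- array(crossprod(cache$cols, gm), dim(w))
  db <- colSums(gm)
  dcols <- gm %*% t(matrix(w, kh * kw * Cin, Cout))
  # col2im: accumulate patch gradients back into the (padded) input
  pd <- cache$x_dim
  xp_dim <- c(pd[1] + 2L * cache$pad, pd[2] + 2L * cache$pad, pd[3])
  dx <- array(0, xp_dim)
  i0 <- seq.int(1L, by = cache$stride, length.out = go[1])
  j0 <- seq.int(1L, by = cache$stride, length.out = go[2])
  col <- 1L
  for (ci in seq_len(Cin)) for (dj in 0:(kw - 1L)) for (di in 0:(kh - 1L)) {
    dx[i0 + di, j0 + dj, ci] <- dx[i0 + di, j0 + dj, ci] +
      matrix(dcols[, col], go[1], go[2])
    col <- col + 1L
  }
  if (cache$pad > 0L)
    dx <- dx[cache$pad + seq_len(pd[1]), cache$pad + seq_len(pd[2]), , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

# 2x2 stride-2 transposed convolution (non-overlapping) used for 7->14->28
# mask-branch up-sampling.
deconv2_fwd <- function(x, w, b) {
  d <- dim(x); H <- d[1]; W <- d[2]; Cin <- d[3]; Cout <- dim(w)[4]
  xm <- matrix(x, H * W, Cin)
  out <- array(0, c(2L * H, 2L * W, Cout))
  for (a in 1:2) for (bb in 1:2) {
    o <- xm %*% w[a, bb, , ]
    o <- sweep(o, 2L, b, "+")    # each output position is hit by exactly one tap
    out[seq.int(a, 2L * H, 2L), seq.int(bb, 2L * W, 2L), ] <- array(o, c(H, W, Cout))
  }
  list(out = out, cache = list(xm = xm, x_dim = d))
}

deconv2_bwd <- function(grad_out, w, cache) {
  d <- cache$x_dim; H <- d[1]; W <- d[2]; Cin <- d[3]; Cout <- dim(w)[4]
  dW <- array(0, dim(w)); db <- numeric(Cout)
  dxm <- matrix(0, H * W, Cin)
  for (a in 1:2) for (bb in 1:2) {
    gm <- matrix(grad_out[seq.int(a, 2L * H, 2L), seq.int(bb, 2L * W, 2L), ],
                 H * W, Cout)
    dW[a, bb, , ] <- crossprod(cache$xm, gm)
    db <- db + colSums(gm)
    dxm <- dxm + gm %*% t(w[a, bb, , ])
  }
  list(dx = array(dxm, d), dW = dW, db = db)
}

relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bwd <- function(grad_out, cache) grad_out * cache

linear_fwd <- function(x, w, b) {
  list(out = sweep(x %*% w, 2L, b, "+"), cache = x)
}
linear_bwd <- function(grad_out, w, cache) {
  list(dx = grad_out %*% t(w), dW = crossprod(cache, grad_out), db = colSums(grad_out))
}

# Nearest-neighbour x2 up-sampling (FPN top-down path).
upsample_nn2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , drop = FALSE]
}
upsample_nn2_bwd <- function(grad_out) {
  d <- dim(grad_out)
  ri <- rep(seq_len(d[1] / 2L), each = 2L)
  out <- array(0, c(d[1] / 2L, d[2] / 2L, d[3]))
  for (ch in seq_len(d[3]))
    out[, , ch] <- t(rowsum(t(rowsum(grad_out[, , ch], ri)), ri))
  out
}

# He-normal initialisation; draws from the R global stream.
init_conv <- function(kh, kw, cin, cout, scale = 1) {
  array(stats::rnorm(kh * kw * cin * cout, sd = scale * sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}
init_linear <- function(din, dout, scale = 1) {
  matrix(stats::rnorm(din * dout, sd = scale * sqrt(2 / din)), din, dout)
}

# Numerically stable binary cross-entropy with logits; returns the mean and
# the per-element gradient d(mean BCE)/d(logit) = (sigmoid(x) - y)/n.
bce_with_logits <- function(logits, labels) {
  if (any(!labels %in% c(0, 1))) stop("bce_with_logits: labels must be 0/1")
  if (any(!is.finite(logits))) stop("bce_with_logits: non-finite logits")
  x <- as.numeric(logits); y <- as.numeric(labels)
  loss <- mean(pmax(x, 0) - x * y + log1p(exp(-abs(x))))
  grad <- (stats::plogis(x) - y) / length(x)
  list(loss = loss, grad = grad)
}

smooth_l1 <- function(pred, target) {
  d <- as.numeric(pred - target)
  per <- ifelse(abs(d) < 1, 0.5 * d^2, abs(d) - 0.5)
  list(loss = mean(per), grad = ifelse(abs(d) < 1, d, sign(d)) / length(d))
}

sigmoid <- function(x) stats::plogis(x)

# Recursive map over two parameter trees of identical shape.
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE)
    out
  } else f(a, b)
}

tree_zero_like <- function(a) {
  if (is.list(a)) lapply(a, tree_zero_like)
  else { z <- a; z[] <- 0; z }
}

# SGD with momentum: v <- mu v - lr g ; p <- p + v. Operates on whole trees.
sgd_step <- function(params, grads, state, lr, momentum, weight_decay = 0) {
  if (weight_decay > 0)
    grads <- tree_map2(function(g, p) g + weight_decay * p, grads, params)
  state <- tree_map2(function(v, g) momentum * v - lr * g, state, grads)
  params <- tree_map2(function(p, v) p + v, params, state)
  list(params = params, state = state)
}
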