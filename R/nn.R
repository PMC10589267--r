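# Neural-network primitives: channel-first 1D convolution (im2col + BLAS
# matmul), max pooling, layer normalization, LSTM cell, dense layers,
# dropout, Huber loss, Adam. Forward functions return caches consumed by
# the matching backward functions; gradients are finite-difference checked
# in the test suite.

# ---- conv1d, stride s, zero "same" padding (output length ceil(L/s)) ----

# x: (C, L, B); W: (C_out, C*K) rows index (c fastest, then k); b: C_out.
# Heavy lifting (im2col + BLAS matmul, scatter-add) is in compiled code;
# the input x is cached for the backward pass (smaller than the patch
# matrix by a factor of K).
conv1d_forward <- function(x, W, b, K, stride) {
  d <- dim(x)
  out <- cpp_conv1d_forward(x, W, b, d[1], d[2], d[3], K, stride)
  list(y = out$y, cache = list(x = x, dims = d, K = K, stride = stride))
}

conv1d_backward <- function(dy, W, cache) {
  d <- cache$dims
  cpp_conv1d_backward(cache$x, W, dy, d[1], d[2], d[3], cache$K,
                      cache$stride)
}

# ---- max pooling width/stride p along L (L divisible by p) ----

maxpool_forward <- function(x, p = 2L) {
  d <- dim(x)
  stopifnot(d[2] %% p == 0L)
  out <- cpp_maxpool_forward(x, d[1], d[2], d[3], p)
  list(y = out$y, cache = list(arg = out$arg, p = p, dims = d))
}

maxpool_backward <- function(dy, cache) {
  d <- cache$dims
  cpp_maxpool_backward(dy, cache$arg, d[1], d[2], d[3], cache$p)
}

# ---- misc layers ----

`%||%` <- function(a, b) if (is.null(a)) b else a

# layer norm over the feature dimension; x: (F, B)
layernorm_forward <- function(x, g, b, eps = 1e-5) {
  mu <- colMeans(x)
  xc <- x - rep(mu, each = nrow(x))
  v <- colMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(istd, each = nrow(x))
  y <- xhat * g + b
  list(y = y, cache = list(xhat = xhat, istd = istd, g = g))
}

layernorm_backward <- function(dy, cache) {
  xhat <- cache$xhat; istd <- cache$istd; g <- cache$g
  Fn <- nrow(dy)
  dg <- rowSums(dy * xhat)
  db <- rowSums(dy)
  dxhat <- dy * g
  dx <- (dxhat - rep(colMeans(dxhat), each = Fn) -
         xhat * rep(colMeans(dxhat * xhat), each = Fn)) *
    rep(istd, each = Fn)
  list(dx = dx, dg = dg, db = db)
}

dense_forward <- function(x, W, b) list(y = W %*% x + b, cache = x)
dense_backward <- function(dy, W, cache) {
  list(dx = crossprod(W, dy), dW = tcrossprod(dy, cache), db = rowSums(dy))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# LSTM cell; u: (F, B) input, h/c: (H, B)
lstm_forward <- function(u, h, c, Wx, Wh, b) {
  H <- nrow(Wh)
  z <- Wx %*% u + Wh %*% h + b
  H4 <- nrow(z); Hn <- H4 %/% 4L
  i <- sigmoid(z[seq_len(Hn), , drop = FALSE])
  f <- sigmoid(z[Hn + seq_len(Hn), , drop = FALSE])
  g <- tanh(z[2L * Hn + seq_len(Hn), , drop = FALSE])
  o <- sigmoid(z[3L * Hn + seq_len(Hn), , drop = FALSE])
  cn <- f * c + i * g
  tc <- tanh(cn)
  hn <- o * tc
  list(h = hn, c = cn,
       cache = list(u = u, h_prev = h, c_prev = c, i = i, f = f, g = g,
                    o = o, tc = tc))
}

lstm_backward <- function(dh, dc_next, cache, Wx, Wh) {
  i <- cache$i; f <- cache$f; g <- cache$g; o <- cache$o; tc <- cache$tc
  do <- dh * tc
  dc <- dh * o * (1 - tc * tc) + dc_next
  di <- dc * g
  dg <- dc * i
  df <- dc * cache$c_prev
  dc_prev <- dc * f
  dzi <- di * i * (1 - i)
  dzf <- df * f * (1 - f)
  dzg <- dg * (1 - g * g)
  dzo <- do * o * (1 - o)
  dz <- rbind(dzi, dzf, dzg, dzo)
  list(du = crossprod(Wx, dz),
       dh_prev = crossprod(Wh, dz),
       dc_prev = dc_prev,
       dWx = tcrossprod(dz, cache$u),
       dWh = tcrossprod(dz, cache$h_prev),
       db = rowSums(dz))
}

# ---- Huber loss (mean over components and batch) ----

huber_loss <- function(pred, target, delta = 1) {
  r <- pred - target
  a <- abs(r)
  quad <- a <= delta
  l <- ifelse(quad, 0.5 * r * r, delta * (a - 0.5 * delta))
  grad <- ifelse(quad, r, delta * sign(r)) / length(r)
  list(loss = mean(l), grad = grad)
}

# ---- Adam over a flat named list of arrays ----

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gval <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gval
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gval * gval
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
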