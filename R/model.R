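#' Model architecture configuration
#'
#' The network follows the i2f / fusion / recurrent / f2o layout: a
#' convolutional block of `conv_layers` layers (each: 1D convolution with
#' `n_filters` filters of size `kernel` and stride 2, ReLU, dropout, max
#' pooling of width `pool`) processing the two channel spectra jointly as
#' input channels of one stack; a fusion layer concatenating the flattened
#' features with the last action followed by layer normalization; one LSTM
#' cell of width `hidden`; and an output head (layer norm, dense + dropout
#' + ReLU of width `head_hidden`, dense + tanh of width `action_dim`).
#' Predictions are therefore always inside `(-1, 1)^action_dim` and the
#' same parameters process sequences of any length.
#'
#' @param input_len model input spectrum length (after preprocessing).
#' @param in_channels number of parallel channels m (input channels of the
#'   convolution).
#' @param action_dim number of shim components `m*n` (output width).
#' @param n_filters,kernel,conv_layers,pool convolution block shape
#'   (defaults 64 filters, kernel 41, 3 layers, pooling width 2).
#' @param hidden LSTM width (default 256).
#' @param head_hidden width of the head's hidden dense layer (default
#'   `hidden`).
#' @param dropout dropout rate used after each conv ReLU and in the head.
#' @return list of class `pedr_model_config` with the derived feature
#'   length `feat_len`.
#' @export
pedr_model_config <- function(input_len, in_channels = 2, action_dim = 12,
                              n_filters = 64, kernel = 41, conv_layers = 3,
                              pool = 2, hidden = 256, head_hidden = hidden,
                              dropout = 0.2) {
  L <- input_len
  for (i in seq_len(conv_layers)) {
    L <- ceiling(L / 2)
    if (L %% pool != 0)
      stop("input_len ", input_len, " does not survive ", conv_layers,
           " conv+pool stages; choose a length divisible by ",
           (2 * pool)^conv_layers)
    L <- L %/% pool
  }
  structure(list(input_len = input_len, in_channels = in_channels,
                 action_dim = action_dim, n_filters = n_filters,
                 kernel = kernel, conv_layers = conv_layers, pool = pool,
                 hidden = hidden, head_hidden = head_hidden,
                 dropout = dropout, conv_out_len = L,
                 feat_len = L * n_filters),
            class = "pedr_model_config")
}

#' Initialize model parameters
#'
#' He-scaled Gaussian initialization for convolution and the hidden dense
#' layer, uniform `+/- 1/sqrt(hidden)` for the LSTM with the forget-gate
#' bias at +1, and a small final layer (so initial predictions start near
#' `tanh(0) = 0`).
#'
#' @param cfg a [pedr_model_config()].
#' @param seed integer seed.
#' @return flat named list of weight arrays of class `pedr_params`.
#' @export
init_params <- function(cfg, seed = 1) {
  with_seed(seed, {
    p <- list()
    cin <- cfg$in_channels
    for (l in seq_len(cfg$conv_layers)) {
      fan_in <- cin * cfg$kernel
      p[[paste0("conv", l, ".W")]] <-
        matrix(stats::rnorm(cfg$n_filters * fan_in, 0, sqrt(2 / fan_in)),
               cfg$n_filters, fan_in)
      p[[paste0("conv", l, ".b")]] <- numeric(cfg$n_filters)
      cin <- cfg$n_filters
    }
    Ff <- cfg$feat_len + cfg$action_dim
    p[["ln_f.g"]] <- rep(1, Ff); p[["ln_f.b"]] <- numeric(Ff)
    H <- cfg$hidden
    lim <- 1 / sqrt(H)
    p[["lstm.Wx"]] <- matrix(stats::runif(4 * H * Ff, -lim, lim), 4 * H, Ff)
    p[["lstm.Wh"]] <- matrix(stats::runif(4 * H * H, -lim, lim), 4 * H, H)
    b <- numeric(4 * H); b[H + seq_len(H)] <- 1   # forget gate bias
    p[["lstm.b"]] <- b
    p[["ln_h.g"]] <- rep(1, H); p[["ln_h.b"]] <- numeric(H)
    p[["fc1.W"]] <- matrix(stats::rnorm(cfg$head_hidden * H, 0, sqrt(2 / H)),
                           cfg$head_hidden, H)
    p[["fc1.b"]] <- numeric(cfg$head_hidden)
    p[["fc2.W"]] <- matrix(stats::rnorm(cfg$action_dim * cfg$head_hidden, 0,
                                        0.01),
                           cfg$action_dim, cfg$head_hidden)
    p[["fc2.b"]] <- numeric(cfg$action_dim)
    class(p) <- "pedr_params"
    p
  })
}

#' Fresh (zero) recurrent state
#' @param cfg a [pedr_model_config()].
#' @param batch batch size.
#' @return list with `h` and `c` matrices (`hidden x batch`).
#' @export
init_hidden <- function(cfg, batch = 1) {
  list(h = matrix(0, cfg$hidden, batch), c = matrix(0, cfg$hidden, batch))
}

# internal full forward of one timestep; x: (C, L, B), a: (A, B)
nn_step <- function(params, cfg, x, a, hc, train = FALSE) {
  cache <- list()
  z <- x
  for (l in seq_len(cfg$conv_layers)) {
    cv <- conv1d_forward(z, params[[paste0("conv", l, ".W")]],
                         params[[paste0("conv", l, ".b")]],
                         cfg$kernel, 2L)
    rd <- cpp_relu_dropout(cv$y, cfg$dropout, train)
    mp <- maxpool_forward(rd$y, cfg$pool)
    cache[[paste0("conv", l)]] <- list(cv = cv$cache, mult = rd$mult,
                                       mp = mp$cache)
    z <- mp$y
  }
  B <- dim(z)[3]
  flat <- z; dim(flat) <- c(cfg$feat_len, B)
  fused <- rbind(flat, a)
  ln1 <- layernorm_forward(fused, params[["ln_f.g"]], params[["ln_f.b"]])
  ls <- lstm_forward(ln1$y, hc$h, hc$c, params[["lstm.Wx"]],
                     params[["lstm.Wh"]], params[["lstm.b"]])
  ln2 <- layernorm_forward(ls$h, params[["ln_h.g"]], params[["ln_h.b"]])
  d1 <- dense_forward(ln2$y, params[["fc1.W"]], params[["fc1.b"]])
  rd2 <- cpp_relu_dropout(d1$y, cfg$dropout, train)
  d2 <- dense_forward(rd2$y, params[["fc2.W"]], params[["fc2.b"]])
  y <- tanh(d2$y)
  cache$fusion <- list(ln1 = ln1$cache, B = B)
  cache$lstm <- ls$cache
  cache$head <- list(ln2 = ln2$cache, d1 = d1$cache, mult = rd2$mult,
                     d2 = d2$cache, y = y)
  list(y = y, h = ls$h, c = ls$c, cache = cache)
}

# backward of one timestep. dy: (A, B) loss gradient on the prediction;
# dh_next/dc_next: recurrent gradients flowing from the next timestep.
# Returns per-parameter gradients plus dh/dc to pass to step t-1.
nn_step_backward <- function(params, cfg, cache, dy, dh_next, dc_next) {
  gd <- list()
  hd <- cache$head
  da2 <- dy * (1 - hd$y * hd$y)
  bk2 <- dense_backward(da2, params[["fc2.W"]], hd$d2)
  gd[["fc2.W"]] <- bk2$dW; gd[["fc2.b"]] <- bk2$db
  dr1 <- bk2$dx * hd$mult
  bk1 <- dense_backward(dr1, params[["fc1.W"]], hd$d1)
  gd[["fc1.W"]] <- bk1$dW; gd[["fc1.b"]] <- bk1$db
  bln2 <- layernorm_backward(bk1$dx, hd$ln2)
  gd[["ln_h.g"]] <- bln2$dg; gd[["ln_h.b"]] <- bln2$db
  dh <- bln2$dx + dh_next
  bls <- lstm_backward(dh, dc_next, cache$lstm, params[["lstm.Wx"]],
                       params[["lstm.Wh"]])
  gd[["lstm.Wx"]] <- bls$dWx; gd[["lstm.Wh"]] <- bls$dWh
  gd[["lstm.b"]] <- bls$db
  bln1 <- layernorm_backward(bls$du, cache$fusion$ln1)
  gd[["ln_f.g"]] <- bln1$dg; gd[["ln_f.b"]] <- bln1$db
  B <- cache$fusion$B
  dflat <- bln1$dx[seq_len(cfg$feat_len), , drop = FALSE]
  da <- bln1$dx[cfg$feat_len + seq_len(cfg$action_dim), , drop = FALSE]
  dz <- dflat
  dim(dz) <- c(cfg$n_filters, cfg$conv_out_len, B)
  for (l in rev(seq_len(cfg$conv_layers))) {
    cc <- cache[[paste0("conv", l)]]
    dmp <- maxpool_backward(dz, cc$mp)
    drl <- dmp * cc$mult
    bcv <- conv1d_backward(drl, params[[paste0("conv", l, ".W")]], cc$cv)
    gd[[paste0("conv", l, ".W")]] <- bcv$dW
    gd[[paste0("conv", l, ".b")]] <- bcv$db
    dz <- bcv$dx
  }
  list(grads = gd, dh_prev = bls$dh_prev, dc_prev = bls$dc_prev, da = da)
}

#' Run one model step (one sequence entity)
#'
#' Consumes one preprocessed spectrum pair together with the action that
#' produced it and the carried recurrent state, and returns the shim
#' correction prediction in `(-1, 1)^action_dim` plus the evolved state.
#' With `train_mode = FALSE` (dropout disabled) the call is deterministic.
#'
#' @param params [init_params()] weights.
#' @param cfg [pedr_model_config()].
#' @param spectra matrix `input_len x in_channels` (one entity's pair), or
#'   array `(in_channels, input_len, B)` for a batch.
#' @param last_action normalized action vector (length `action_dim`) or
#'   `(action_dim x B)` matrix.
#' @param hidden state from [init_hidden()] or a previous step.
#' @param train_mode enable dropout.
#' @return list with `prediction` and `hidden` (the new state).
#' @export
forward_step <- function(params, cfg, spectra, last_action, hidden,
                         train_mode = FALSE) {
  if (is.matrix(spectra) && ncol(spectra) == cfg$in_channels) {
    if (nrow(spectra) != cfg$input_len)
      stop("spectra must have ", cfg$input_len, " rows, got ", nrow(spectra))
    x <- array(t(spectra), c(cfg$in_channels, cfg$input_len, 1L))
    a <- matrix(last_action, ncol = 1)
  } else {
    x <- spectra
    if (dim(x)[2] != cfg$input_len)
      stop("spectra length mismatch: expected ", cfg$input_len)
    a <- last_action
  }
  st <- nn_step(params, cfg, x, a, hidden, train = train_mode)
  list(prediction = if (ncol(a) == 1) as.numeric(st$y) else st$y,
       hidden = list(h = st$h, c = st$c))
}

# forward a whole batched sequence; xs: list over entities of (C, L, B),
# as_: list over entities of (A, B). Returns predictions per step and
# caches (if keep_cache).
nn_sequence_forward <- function(params, cfg, xs, as_, train = FALSE,
                                keep_cache = FALSE) {
  Tn <- length(xs)
  B <- dim(xs[[1]])[3]
  hc <- init_hidden(cfg, B)
  preds <- vector("list", Tn)
  caches <- if (keep_cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    st <- nn_step(params, cfg, xs[[t]], as_[[t]], hc, train = train)
    preds[[t]] <- st$y
    hc <- list(h = st$h, c = st$c)
    if (keep_cache) caches[[t]] <- st$cache
  }
  list(preds = preds, caches = caches)
}

# full BPTT for one batch; dys: list over entities of (A, B) gradients
nn_sequence_backward <- function(params, cfg, caches, dys) {
  Tn <- length(caches)
  B <- dim(dys[[1]])[2]
  acc <- NULL
  dh <- matrix(0, cfg$hidden, B); dc <- matrix(0, cfg$hidden, B)
  for (t in rev(seq_len(Tn))) {
    bk <- nn_step_backward(params, cfg, caches[[t]], dys[[t]], dh, dc)
    dh <- bk$dh_prev; dc <- bk$dc_prev
    if (is.null(acc)) {
      acc <- bk$grads
    } else {
      for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + bk$grads[[nm]]
    }
  }
  acc
}
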