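tiny_cfg <- function(dropout = 0) {
  pedr_model_config(input_len = 64, in_channels = 2, action_dim = 4,
                    n_filters = 6, kernel = 5, conv_layers = 2, pool = 2,
                    hidden = 12, head_hidden = 10, dropout = dropout)
}

rand_inputs <- function(cfg, Tn, B, seed = 1) {
  parashim:::with_seed(seed, list(
    xs = lapply(seq_len(Tn), function(t)
      array(stats::rnorm(cfg$in_channels * cfg$input_len * B),
            c(cfg$in_channels, cfg$input_len, B))),
    as_ = lapply(seq_len(Tn), function(t)
      matrix(stats::rnorm(cfg$action_dim * B, 0, 0.3), cfg$action_dim, B)),
    tgt = matrix(stats::rnorm(cfg$action_dim * B, 0, 0.3),
                 cfg$action_dim, B)))
}

test_that("forward step: determinism, bounds, zero head, input checks", {
  cfg <- tiny_cfg()
  p <- init_params(cfg, seed = 3)
  h0 <- init_hidden(cfg)
  spec <- matrix(stats::rnorm(64 * 2), 64, 2)
  a <- rep(0.1, 4)
  s1 <- forward_step(p, cfg, spec, a, h0)
  s2 <- forward_step(p, cfg, spec, a, h0)
  expect_identical(s1$prediction, s2$prediction)       # eval-mode determinism
  expect_true(all(abs(s1$prediction) < 1))
  # zeroed final layer forces tanh(0) = 0 predictions
  p0 <- p
  p0[["fc2.W"]][] <- 0; p0[["fc2.b"]][] <- 0
  expect_equal(forward_step(p0, cfg, spec, a, h0)$prediction, rep(0, 4))
  expect_error(forward_step(p, cfg, matrix(0, 32, 2), a, h0), "rows")
})

test_that("predictions stay inside (-1, 1) for any sequence length", {
  cfg <- tiny_cfg()
  p <- init_params(cfg, seed = 5)
  for (Tn in c(1, 3, 10)) {
    inp <- rand_inputs(cfg, Tn, 4, seed = Tn)
    fw <- parashim:::nn_sequence_forward(p, cfg, inp$xs, inp$as_)
    for (y in fw$preds) expect_true(all(abs(y) < 1))
    expect_length(fw$preds, Tn)
  }
})

test_that("step-by-step forwarding equals the batched unrolled pass", {
  cfg <- tiny_cfg()
  p <- init_params(cfg, seed = 7)
  Tn <- 10
  inp <- rand_inputs(cfg, Tn, 1, seed = 2)
  fw <- parashim:::nn_sequence_forward(p, cfg, inp$xs, inp$as_)
  hc <- init_hidden(cfg)
  for (t in seq_len(Tn)) {
    spec <- t(inp$xs[[t]][, , 1])
    st <- forward_step(p, cfg, spec, inp$as_[[t]][, 1], hc)
    hc <- st$hidden
    if (t == Tn) final_step <- st$prediction
  }
  expect_equal(final_step, as.numeric(fw$preds[[Tn]]), tolerance = 1e-6)
})

test_that("analytic gradients match finite differences", {
  cfg <- tiny_cfg(dropout = 0)
  p <- init_params(cfg, seed = 11)
  inp <- rand_inputs(cfg, 3, 2, seed = 4)
  loss_fn <- function(pp) {
    fw <- parashim:::nn_sequence_forward(pp, cfg, inp$xs, inp$as_)
    mean(vapply(fw$preds, function(y)
      parashim:::huber_loss(y, inp$tgt)$loss, numeric(1)))
  }
  fw <- parashim:::nn_sequence_forward(p, cfg, inp$xs, inp$as_,
                                       keep_cache = TRUE)
  dys <- lapply(fw$preds, function(y)
    parashim:::huber_loss(y, inp$tgt)$grad / 3)
  gr <- parashim:::nn_sequence_backward(p, cfg, fw$caches, dys)
  eps <- 1e-6
  set.seed(9)
  for (nm in names(p)) {
    for (i in sample(length(p[[nm]]), min(3, length(p[[nm]])))) {
      pp <- p
      pp[[nm]][i] <- pp[[nm]][i] + eps; lp <- loss_fn(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps; lm <- loss_fn(pp)
      num <- (lp - lm) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-3,
                   label = paste("grad", nm, i))
    }
  }
})

test_that("Huber loss is zero at zero residual and matches its cases", {
  y <- matrix(c(0.2, -0.4), 2, 1)
  expect_equal(parashim:::huber_loss(y, y)$loss, 0)
  # quadratic branch below delta, linear above
  hl <- parashim:::huber_loss(matrix(0.4), matrix(0), delta = 1)
  expect_equal(hl$loss, 0.5 * 0.4^2)
  hl2 <- parashim:::huber_loss(matrix(3), matrix(0), delta = 1)
  expect_equal(hl2$loss, 1 * (3 - 0.5))
})

test_that("curriculum schedule matches the printed 4-to-10 plan", {
  tc <- pedr_train_config(epochs = 100)
  lens <- vapply(1:100, function(e) curriculum_length(tc, e), numeric(1))
  expect_equal(unique(lens[1:25]), 4)
  expect_equal(unique(lens[26:50]), 6)
  expect_equal(unique(lens[51:75]), 8)
  expect_equal(unique(lens[76:100]), 10)
  expect_true(all(lens %in% c(4, 6, 8, 10)))
})

test_that("short training runs reduce validation loss on most seeds", {
  # tiny world so 4 epochs stay cheap; the check is a smoke statistic:
  # training beats the epoch-1 validation loss in at least 4 of 5 seeds
  cfg <- reduced_world_config()
  cfg$world$L <- 128; cfg$world$sweep_hz <- 128
  sp <- build_world(cfg)
  wins <- 0L
  for (seed in 1:5) {
    ds <- generate_dataset(sp, 50, seed = seed)
    pcfg <- preprocess_config(roi_size = 128, downsample_factor = 1,
                              target_norm_bound = 2 * abs(ds$ref))
    mcfg <- pedr_model_config(input_len = 128, in_channels = 2,
                              action_dim = 4, n_filters = 6, kernel = 5,
                              conv_layers = 2, pool = 2, hidden = 16,
                              dropout = 0)
    tcfg <- pedr_train_config(epochs = 6, lr = 2e-3, batch_size = 8,
                              curriculum_from = 4, curriculum_to = 4,
                              eval_entities = 4, augment = NULL)
    mod <- train_pedr(ds, sp, mcfg, tcfg, pcfg, seed = seed)
    h <- mod$history
    if (h$val_loss[nrow(h)] < h$val_loss[1]) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
  expect_error(
    train_pedr(structure(list(split = factor(character(),
                                             levels = c("train", "val",
                                                        "test"))),
                         class = "shim_dataset"), sp),
    "non-empty")
})

test_that("checkpoints round-trip the model bundle", {
  cfg <- tiny_cfg()
  p <- init_params(cfg, 1)
  model <- structure(list(params = p, model_cfg = cfg,
                          pcfg = preprocess_config(64, 1,
                                                   target_norm_bound = 1),
                          train_cfg = pedr_train_config(epochs = 1),
                          history = data.frame(), seed = 1),
                     class = "pedr_model")
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_equal(back$params, model$params)
  expect_equal(back$model_cfg, model$model_cfg)
})
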