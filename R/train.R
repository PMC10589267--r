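#' Training configuration
#'
#' Defaults mirror the training recipe: 100 epochs, Adam at learning rate
#' 1e-4 reduced on plateau (factor 0.5, patience 5 epochs on validation
#' loss), batch size 256, Huber loss (delta 1), and a sequence-length
#' curriculum growing from 4 to 10 entities by +2 every 25 epochs.
#'
#' @param epochs number of epochs.
#' @param lr initial Adam learning rate.
#' @param batch_size minibatch size.
#' @param huber_delta Huber loss transition point.
#' @param curriculum_from,curriculum_to,curriculum_increment,curriculum_step_epochs
#'   sequence length (entities) schedule: length at epoch `e` is
#'   `min(to, from + increment * floor((e-1)/step_epochs))`.
#' @param plateau_factor,plateau_patience reduce-on-plateau scheduler.
#' @param lr_step_epochs optional fixed step decay: epochs at whose start
#'   the learning rate is multiplied by `plateau_factor`.
#' @param eval_entities sequence length used for validation/test
#'   evaluation (default 6 = initial entity + 5 random steps, matching the
#'   episode's random phase).
#' @param action_sigma_frac sigma policy for random sequence actions as a
#'   fraction of Ref (default: the dataset's distortion policy).
#' @param augment an [augment_config()], or NULL to disable augmentation.
#' @return list of class `pedr_train_config`.
#' @export
pedr_train_config <- function(epochs = 100, lr = 1e-4, batch_size = 256,
                              huber_delta = 1, curriculum_from = 4,
                              curriculum_to = 10, curriculum_increment = 2,
                              curriculum_step_epochs = 25,
                              plateau_factor = 0.5, plateau_patience = 5,
                              lr_step_epochs = integer(),
                              eval_entities = 6, action_sigma_frac = NULL,
                              augment = augment_config()) {
  structure(as.list(environment()), class = "pedr_train_config")
}

#' Sequence length (entities) prescribed by the curriculum at an epoch
#' @param tc a [pedr_train_config()].
#' @param epoch epoch number (1-based).
#' @export
curriculum_length <- function(tc, epoch) {
  min(tc$curriculum_to,
      tc$curriculum_from +
        tc$curriculum_increment * ((epoch - 1) %/% tc$curriculum_step_epochs))
}

# ---- internal batched sequence construction -----------------------------

# Build model-ready tensors for samples `idx` of `ds`: sequences of
# `entities` entities with fresh random actions, preprocessed, normalized
# and (optionally) augmented. Returns xs (list over entities of (C,Lc,B)),
# as_ (list of (A,B) normalized actions), target (A,B) normalized.
build_batch_tensors <- function(ds, idx, entities, sp, pcfg, aug = NULL,
                                action_sigma_frac = NULL) {
  B <- length(idx)
  A <- ds$m * ds$n
  Lc <- pcfg$roi_size %/% pcfg$downsample_factor
  sfrac <- action_sigma_frac %||% ds$sigma_frac
  tgt <- t(ds$targets[idx, , drop = FALSE])              # (A, B)
  sdv <- abs(ds$ref) * sfrac
  ch_ent <- vector("list", entities)                     # [[k]][[ch]]: (Lc,B)
  # entity 1: stored unshimmed pair
  e1 <- lapply(seq_len(ds$m), function(ch) {
    mat <- ds$spectra[idx, ch, , drop = FALSE]
    dim(mat) <- c(B, ds$L)
    crop_and_downsample(t(mat), pcfg)
  })
  ch_ent[[1]] <- e1
  actions <- vector("list", entities)
  actions[[1]] <- matrix(0, A, B)
  if (entities > 1) {
    for (k in 2:entities) {
      actions[[k]] <- matrix(stats::rnorm(A * B, 0, sdv), A, B)
      eff <- tgt - actions[[k]]
      mats <- acquire_batch(sp, eff)
      ch_ent[[k]] <- lapply(mats, crop_and_downsample, cfg = pcfg)
    }
  }
  # per-sample normalization from the first (up to) two entities
  head_ent <- ch_ent[seq_len(min(2L, entities))]
  mins <- do.call(pmin, lapply(head_ent, function(e)
    do.call(pmin, lapply(e, function(m) apply(m, 2, min)))))
  maxs <- do.call(pmax, lapply(head_ent, function(e)
    do.call(pmax, lapply(e, function(m) apply(m, 2, max)))))
  rng <- maxs - mins
  if (any(rng <= 0)) stop("degenerate sequence: flat first spectra")
  for (k in seq_len(entities))
    ch_ent[[k]] <- lapply(ch_ent[[k]], function(m)
      (m - rep(mins, each = Lc)) / rep(rng, each = Lc))
  bound <- pcfg$target_norm_bound
  a_norm <- lapply(actions, function(a)
    pmin(pmax(a / bound, -1), 1))
  t_norm <- pmin(pmax(tgt / bound, -1), 1)
  # ---- augmentation (training only) ----
  if (!is.null(aug)) {
    if (aug$z0_shift_range > 0) {
      s <- sample.int(2L * aug$z0_shift_range + 1L, B, replace = TRUE) -
        aug$z0_shift_range - 1L
      ind <- (outer(0:(Lc - 1), -s, "+") %% Lc) + 1L
      flat <- ind + rep((seq_len(B) - 1L) * Lc, each = Lc)
      for (k in seq_len(entities))
        ch_ent[[k]] <- lapply(ch_ent[[k]], function(m)
          matrix(m[flat], Lc, B))
    }
    if (aug$phase1_range > 0) {
      p1 <- stats::runif(B, -aug$phase1_range, aug$phase1_range)
      if (aug$phase1_cycles) p1 <- 2 * pi * p1
      ramp0 <- (seq_len(Lc) - 1) / (Lc - 1) - 0.5
      rot <- exp(1i * outer(ramp0, p1))
      h <- numeric(Lc)
      if (Lc %% 2 == 0) { h[c(1, Lc / 2 + 1)] <- 1; h[2:(Lc / 2)] <- 2 }
      else { h[1] <- 1; h[2:((Lc + 1) / 2)] <- 2 }
      for (k in seq_len(entities))
        ch_ent[[k]] <- lapply(ch_ent[[k]], function(m) {
          an <- stats::mvfft(stats::mvfft(m) * h, inverse = TRUE) / Lc
          Re(an * rot)
        })
    }
    if (is.finite(aug$awgn_snr)) {
      for (k in seq_len(entities))
        ch_ent[[k]] <- lapply(ch_ent[[k]], function(m) {
          sds <- apply(abs(m), 2, max) / aug$awgn_snr
          m + matrix(stats::rnorm(length(m)), Lc) * rep(sds, each = Lc)
        })
    }
    if (aug$label_noise > 0)
      t_norm <- t_norm + matrix(stats::runif(A * B, -aug$label_noise,
                                             aug$label_noise), A, B)
    if (aug$interaction_noise > 0 && entities > 1) {
      for (k in 2:entities)
        a_norm[[k]] <- a_norm[[k]] *
          matrix(stats::runif(A * B, 1 - aug$interaction_noise,
                              1 + aug$interaction_noise), A, B)
    }
  }
  xs <- lapply(seq_len(entities), function(k) {
    x <- array(0, c(ds$m, Lc, B))
    for (ch in seq_len(ds$m)) x[ch, , ] <- ch_ent[[k]][[ch]]
    x
  })
  list(xs = xs, as_ = a_norm, target = t_norm)
}

#' Train the shim-regression model
#'
#' Supervised training on the dataset's train split with online sequence
#' construction: every epoch draws fresh random action sequences at the
#' curriculum's current length, preprocesses and augments them, and
#' minimizes the Huber loss between the per-step predictions and the
#' normalized distortion target using Adam. Validation sequences are built
#' once under a fixed seed so that epoch-to-epoch losses are comparable;
#' the returned parameters are the best-on-validation ones.
#'
#' @param ds a [generate_dataset()] result with non-empty train and val
#'   splits.
#' @param sp the virtual spectrometer that generated `ds`.
#' @param model_cfg a [pedr_model_config()]; NULL builds the default for
#'   the dataset's geometry.
#' @param train_cfg a [pedr_train_config()].
#' @param pcfg a [preprocess_config()]; NULL uses defaults with
#'   `target_norm_bound = 2 * ref`.
#' @param seed global seed (controls init, sequence draws, batching and
#'   dropout through independent streams).
#' @param verbose print per-epoch progress.
#' @return object of class `pedr_model`: list with `params` (best on
#'   validation), `final_params`, `model_cfg`, `pcfg`, `train_cfg`,
#'   `history` (data.frame: epoch, curriculum, train_loss, val_loss, lr).
#' @export
train_pedr <- function(ds, sp, model_cfg = NULL, train_cfg =
                         pedr_train_config(), pcfg = NULL, seed = 1,
                       verbose = FALSE) {
  stopifnot(inherits(ds, "shim_dataset"))
  tr_idx <- which(ds$split == "train")
  va_idx <- which(ds$split == "val")
  if (length(tr_idx) == 0 || length(va_idx) == 0)
    stop("dataset needs non-empty train and val splits")
  if (is.null(pcfg))
    pcfg <- preprocess_config(roi_size = min(4096, ds$L),
                              downsample_factor = if (ds$L >= 4096) 2 else 1,
                              target_norm_bound = 2 * abs(ds$ref))
  if (is.null(pcfg$target_norm_bound))
    pcfg$target_norm_bound <- 2 * abs(ds$ref)
  Lc <- pcfg$roi_size %/% pcfg$downsample_factor
  if (is.null(model_cfg))
    model_cfg <- pedr_model_config(input_len = Lc, in_channels = ds$m,
                                   action_dim = ds$m * ds$n)
  tree <- seeded_rng_tree(seed)
  params <- init_params(model_cfg,
                        seed = with_stream(tree, "init",
                                           sample.int(2^31 - 1, 1)))
  opt <- adam_init(params)
  lr <- train_cfg$lr
  # fixed validation tensors (no augmentation)
  val <- with_stream(tree, "eval",
                     build_batch_tensors(ds, va_idx,
                                         train_cfg$eval_entities, sp, pcfg,
                                         action_sigma_frac =
                                           train_cfg$action_sigma_frac))
  best_val <- Inf; best_params <- params; since_improve <- 0L
  hist <- vector("list", train_cfg$epochs)
  for (epoch in seq_len(train_cfg$epochs)) {
    ent <- curriculum_length(train_cfg, epoch)
    if (epoch %in% train_cfg$lr_step_epochs)
      lr <- lr * train_cfg$plateau_factor
    perm <- with_stream(tree, "batches", sample(tr_idx))
    nb <- ceiling(length(perm) / train_cfg$batch_size)
    ep_loss <- 0
    for (bi in seq_len(nb)) {
      lo <- (bi - 1) * train_cfg$batch_size + 1L
      hi <- min(bi * train_cfg$batch_size, length(perm))
      idx <- perm[lo:hi]
      bt <- with_stream(tree, "sequences",
                        build_batch_tensors(ds, idx, ent, sp, pcfg,
                                            aug = train_cfg$augment,
                                            action_sigma_frac =
                                              train_cfg$action_sigma_frac))
      fw <- with_stream(tree, "dropout",
                        nn_sequence_forward(params, model_cfg, bt$xs,
                                            bt$as_, train = TRUE,
                                            keep_cache = TRUE))
      dys <- vector("list", ent)
      bl <- 0
      for (t in seq_len(ent)) {
        hl <- huber_loss(fw$preds[[t]], bt$target, train_cfg$huber_delta)
        dys[[t]] <- hl$grad / ent
        bl <- bl + hl$loss / ent
      }
      gr <- nn_sequence_backward(params, model_cfg, fw$caches, dys)
      upd <- adam_step(params, gr, opt, lr)
      params <- upd$params; opt <- upd$state
      ep_loss <- ep_loss + bl * length(idx)
    }
    ep_loss <- ep_loss / length(perm)
    # validation loss on the final step's prediction
    vfw <- nn_sequence_forward(params, model_cfg, val$xs, val$as_)
    vl <- huber_loss(vfw$preds[[length(vfw$preds)]], val$target,
                     train_cfg$huber_delta)$loss
    if (vl < best_val - 1e-12) {
      best_val <- vl; best_params <- params; since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= train_cfg$plateau_patience) {
        lr <- lr * train_cfg$plateau_factor
        since_improve <- 0L
      }
    }
    hist[[epoch]] <- data.frame(epoch = epoch, curriculum = ent,
                                train_loss = ep_loss, val_loss = vl,
                                lr = lr)
    if (verbose)
      message(sprintf("epoch %3d  len %2d  train %.5f  val %.5f  lr %.2g",
                      epoch, ent, ep_loss, vl, lr))
  }
  structure(list(params = best_params, final_params = params,
                 model_cfg = model_cfg, pcfg = pcfg, train_cfg = train_cfg,
                 history = do.call(rbind, hist), seed = seed,
                 best_val = best_val,
                 ds_info = list(n_samples = nrow(ds$targets),
                                seed = ds$seed,
                                sigma_frac = ds$sigma_frac, L = ds$L,
                                m = ds$m, n = ds$n)),
            class = "pedr_model")
}

#' Evaluate a trained model on a dataset split
#'
#' Rebuilds evaluation sequences under a fixed seed (the same protocol as
#' training-time validation: `eval_entities` entities with fresh random
#' actions, no augmentation), runs the model in eval mode and reports the
#' normalized MAE (in `[0, 1]`) and the direction ratio of the final-step
#' predictions.
#'
#' @param model a [train_pedr()] result.
#' @param ds the dataset.
#' @param sp the virtual spectrometer.
#' @param split which split to evaluate (default "test").
#' @param seed evaluation seed.
#' @param entities sequence length (default: the training config's).
#' @return list with `mae`, `dir`, `pred` (normalized, A x B) and
#'   `target` (normalized).
#' @export
evaluate_model <- function(model, ds, sp, split = "test", seed = 99,
                           entities = NULL) {
  idx <- which(ds$split == split)
  if (length(idx) == 0) stop("split '", split, "' is empty")
  if (is.null(entities)) entities <- model$train_cfg$eval_entities
  bt <- with_seed(seed,
                  build_batch_tensors(ds, idx, entities, sp, model$pcfg,
                                      action_sigma_frac =
                                        model$train_cfg$action_sigma_frac))
  fw <- nn_sequence_forward(model$params, model$model_cfg, bt$xs, bt$as_)
  pred <- fw$preds[[length(fw$preds)]]
  list(mae = mean(abs(pred - bt$target)),
       dir = direction_ratio(pred, bt$target),
       pred = pred, target = bt$target)
}

#' Save / load a model checkpoint
#'
#' Bundles the weights with the model, preprocessing and training
#' configurations so inference is reproducible.
#'
#' @param model a `pedr_model`.
#' @param path file path (RDS container).
#' @return `path` invisibly; `load_checkpoint` returns the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "pedr_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "pedr_model"))
  model
}
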