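#' Episode configuration
#'
#' @param r number of random shim offset steps (>= 1).
#' @param p number of predictive steps (>= 1). Total acquisitions per
#'   episode are `r+p+1` (the initial unshimmed spectrum included);
#'   the defaults r = 5, p = 4 give the 10-acquisition budget.
#' @param action_sigma_frac sigma of the random actions as a fraction of
#'   Ref (default 1/3, the dataset policy).
#' @param retain which prediction is the episode's final answer:
#'   `"last"` (the last predictive step) or `"best"` (the action of the
#'   step with the smallest summed FWHM).
#' @return list of class `episode_config`.
#' @export
episode_config <- function(r = 5, p = 4, action_sigma_frac = 1 / 3,
                           retain = c("last", "best")) {
  stopifnot(r >= 1, p >= 1)
  retain <- match.arg(retain)
  structure(list(r = as.integer(r), p = as.integer(p),
                 action_sigma_frac = action_sigma_frac, retain = retain),
            class = "episode_config")
}

# preprocess one acquired pair into a model input matrix (Lc x m)
episode_input <- function(specs, pcfg) {
  vapply(specs, function(s) crop_and_downsample(s$intensities, pcfg),
         numeric(pcfg$roi_size %/% pcfg$downsample_factor))
}

#' Run one AI-driven shimming episode
#'
#' The random-then-predictive loop: acquire the unshimmed pair `u(0)`,
#' apply `r` Gaussian random shim offsets (feeding every observation and
#' its action to the model so the recurrent state accumulates a shimming
#' history), then `p` predictive steps where the denormalized model
#' prediction is used as the next action. Consumes exactly `r+p+1`
#' acquisitions.
#'
#' @param sp a [virtual_spectrometer()] with the episode's distortion
#'   already applied via [set_distortion()].
#' @param model a trained [train_pedr()] model (or a list with `params`,
#'   `model_cfg`, `pcfg` — e.g. an oracle stub for testing).
#' @param cfg an [episode_config()].
#' @param predict_fn optional override: `function(input, a_norm, hidden)`
#'   returning `list(prediction, hidden)`; defaults to the model's
#'   [forward_step()]. Used to plug oracle predictors into the loop.
#' @return object of class `episode_result`: per-step `actions` (raw mA),
#'   `fwhm` matrix (steps x channels), `initial_peak`/`final_peak`,
#'   `final_action`, `final_prediction_norm`, `acquisitions`, `success`,
#'   and (when the true distortion is known) `dir` and `mae`.
#' @export
run_pedr_episode <- function(sp, model, cfg = episode_config(),
                             predict_fn = NULL) {
  stopifnot(inherits(sp, "virtual_spectrometer"))
  pcfg <- model$pcfg
  bound <- pcfg$target_norm_bound
  A <- sp$m * sp$n
  if (!is.null(model$model_cfg) && model$model_cfg$action_dim != A)
    stop("model action dimension ", model$model_cfg$action_dim,
         " does not match spectrometer m*n = ", A)
  if (is.null(predict_fn))
    predict_fn <- function(input, a_norm, hidden)
      {
        st <- forward_step(model$params, model$model_cfg, input, a_norm,
                           hidden)
        list(prediction = st$prediction, hidden = st$hidden)
      }
  hidden <- if (!is.null(model$model_cfg)) init_hidden(model$model_cfg)
            else NULL
  n_steps <- cfg$r + cfg$p + 1L
  acq0 <- acquisition_count(sp)
  actions <- matrix(0, n_steps, A)
  fw <- matrix(NA_real_, n_steps, sp$m)
  peaks <- matrix(NA_real_, n_steps, sp$m)
  raw_inputs <- vector("list", n_steps)
  sum_fwhm <- rep(NA_real_, n_steps)
  pred <- numeric(A)

  step_observe <- function(a, k) {
    specs <- acquire(sp, a)
    raw_inputs[[k]] <<- episode_input(specs, pcfg)
    for (ch in seq_len(sp$m)) {
      peaks[k, ch] <<- max(specs[[ch]]$intensities)
      w <- try(fwhm(specs[[ch]]), silent = TRUE)
      fw[k, ch] <<- if (inherits(w, "try-error")) NA_real_ else as.numeric(w)
    }
    sum_fwhm[k] <<- sum(fw[k, ])
    invisible(specs)
  }

  # normalization scale from the first two entities (first step uses its own)
  norm_in <- function(k) {
    lim <- min(2L, k)
    m0 <- min(vapply(raw_inputs[seq_len(lim)], min, numeric(1)))
    M <- max(vapply(raw_inputs[seq_len(lim)], max, numeric(1)))
    (raw_inputs[[k]] - m0) / (M - m0)
  }

  for (k in seq_len(n_steps)) {
    if (k == 1) {
      a <- numeric(A)
    } else if (k <= cfg$r + 1L) {
      a <- stats::rnorm(A, 0, abs(sp$ref) * cfg$action_sigma_frac)
    } else {
      a <- denormalize_targets(pred, bound)
    }
    actions[k, ] <- a
    step_observe(a, k)
    a_norm <- pmin(pmax(a / bound, -1), 1)
    st <- predict_fn(norm_in(k), a_norm, hidden)
    pred <- st$prediction
    hidden <- st$hidden
  }
  stopifnot(acquisition_count(sp) - acq0 == n_steps)

  k_final <- if (cfg$retain == "best") which.min(sum_fwhm) else n_steps
  final_action <- actions[k_final, ]
  res <- list(actions = actions, fwhm = fw,
              initial_peak = peaks[1, ], final_peak = peaks[k_final, ],
              initial_fwhm = fw[1, ], final_fwhm = fw[k_final, ],
              final_action = final_action,
              final_prediction_norm = pred,
              acquisitions = n_steps,
              success = all(peaks[k_final, ] > peaks[1, ]))
  S <- sp$S
  if (any(S != 0)) {
    s_norm <- pmin(pmax(S / bound, -1), 1)
    last_pred <- actions[n_steps, ] / bound
    res$dir <- direction_ratio(last_pred, s_norm)
    res$mae <- mean(abs(last_pred - s_norm))
  }
  class(res) <- "episode_result"
  res
}

#' Run a batch of seeded evaluation episodes
#'
#' Draws `n_episodes` fresh distortions (uniform in
#' `[-eval_mult * Ref, eval_mult * Ref]` per component, the evaluation
#' protocol of distortions within twice the reference values; set
#' `eval_gaussian = TRUE` for the Gaussian alternative with sigma
#' `eval_mult * Ref / 3`), runs one episode each, and aggregates SR, DiR
#' and MAE.
#'
#' @param sp virtual spectrometer.
#' @param model trained model.
#' @param n_episodes number of episodes (default 50).
#' @param cfg an [episode_config()].
#' @param seed integer seed.
#' @param eval_mult distortion magnitude in units of Ref (default 2).
#' @param eval_gaussian use the Gaussian draw instead of uniform.
#' @return list with `episodes` (list of `episode_result`), `sr`, `dir`
#'   (mean), `mae` (mean), `initial_fwhm`/`final_fwhm` matrices.
#' @export
run_episode_batch <- function(sp, model, n_episodes = 50,
                              cfg = episode_config(), seed = 1,
                              eval_mult = 2, eval_gaussian = FALSE) {
  episodes <- with_seed(seed, {
    lapply(seq_len(n_episodes), function(i) {
      S <- if (eval_gaussian)
        stats::rnorm(sp$m * sp$n, 0, eval_mult * abs(sp$ref) / 3)
      else
        stats::runif(sp$m * sp$n, -eval_mult * abs(sp$ref),
                     eval_mult * abs(sp$ref))
      set_distortion(sp, S)
      run_pedr_episode(sp, model, cfg)
    })
  })
  set_distortion(sp, numeric(sp$m * sp$n))
  ifw <- t(vapply(episodes, function(e) e$initial_fwhm, numeric(sp$m)))
  ffw <- t(vapply(episodes, function(e) e$final_fwhm, numeric(sp$m)))
  list(episodes = episodes,
       sr = success_rate(episodes),
       dir = mean(vapply(episodes, function(e) e$dir %||% NA_real_,
                         numeric(1)), na.rm = TRUE),
       mae = mean(vapply(episodes, function(e) e$mae %||% NA_real_,
                         numeric(1)), na.rm = TRUE),
       initial_fwhm = ifw, final_fwhm = ffw)
}
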