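#' Default run configuration
#'
#' Nested configuration covering all modules. Every key can be overridden
#' from a YAML file via [load_config()]; unknown keys are rejected.
#'
#' Sections: `world` (grid geometry, shim gains in Hz/mA, coupling,
#' residual distortion spans, line models, receiver), `dataset`
#' (sample count, sigma policy), `preprocess`, `model`, `train`,
#' `episode`, plus a global `seed` and `out_dir`.
#'
#' @return nested named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1,
    out_dir = "parashim_out",
    world = list(
      grid = list(diameter_mm = 1, length_mm = 8, n_radial = 4,
                  n_axial = 64),
      shims = list(
        coils = SHIM_COILS,
        # Hz/mA at the reference coordinate; calibrated so that sigma =
        # Ref/3 distortions inflate the linewidth to ~90 Hz on average
        gains_hz_per_ma = c(X = 2, Y = 2, Z = 7, Z2 = 5, Z3 = 3, Z4 = 2),
        ref_ma = 30),
      coupling = list(epsilon = 0.1, seed = 17),
      distortion = list(z_span_hz = 0, xy_span_hz = 0, seed = 29),
      lines = list(positions_hz = 0, amplitudes = 1, natural_fwhm_hz = 10),
      m = 2,
      L = 8192,
      sweep_hz = 8192,
      receiver = list(snr = Inf, snr_db = FALSE, phase1 = 0,
                      z0_drift_per_acq = 0, leak_coeff = 0)),
    dataset = list(n_samples = 1000, sigma_frac = 1 / 3),
    preprocess = list(roi_size = 4096, downsample_factor = 2),
    model = list(n_filters = 64, kernel = 41, conv_layers = 3, pool = 2,
                 hidden = 256, dropout = 0.2),
    train = list(epochs = 100, lr = 1e-4, batch_size = 256,
                 huber_delta = 1, curriculum_from = 4, curriculum_to = 10,
                 curriculum_increment = 2, curriculum_step_epochs = 25,
                 plateau_factor = 0.5, plateau_patience = 5,
                 eval_entities = 6),
    episode = list(r = 5, p = 4, action_sigma_frac = 1 / 3,
                   eval_mult = 2, eval_gaussian = FALSE, n_episodes = 50)
  ), class = "run_config")
}

# recursively merge user values into defaults, erroring on unknown keys
# and type mismatches; `path` tracks the position for error messages
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user))
    stop("config error at '", path, "': expected a section, got a value")
  for (key in names(user)) {
    here <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(defaults))
      stop("unknown config key: '", here, "'")
    dv <- defaults[[key]]
    uv <- user[[key]]
    # YAML maps of scalars stand in for named numeric/character vectors
    if (!is.list(dv) && is.list(uv) &&
        all(vapply(uv, function(x) length(x) == 1 && !is.list(x),
                   logical(1))))
      uv <- unlist(uv)
    if (is.list(dv) && !is.list(uv) && !is.null(names(dv)))
      stop("config error at '", here, "': expected a section")
    if (is.list(dv)) {
      defaults[[key]] <- merge_config(dv, uv, here)
    } else {
      if (is.character(dv) != is.character(uv))
        stop("config type error at '", here, "': expected ",
             if (is.character(dv)) "character" else "numeric")
      if (!is.character(dv) && !is.numeric(uv) && !is.logical(uv))
        stop("config type error at '", here, "': expected numeric, got '",
             paste(uv, collapse = ","), "'")
      defaults[[key]] <- uv
    }
  }
  defaults
}

#' Load and validate a run configuration from YAML
#'
#' Reads a YAML file, applies it on top of [default_config()], and
#' validates it: unknown keys and type mismatches raise an error naming
#' the offending key path. An empty file yields the full default
#' configuration.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @return a validated `run_config`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(default_config())
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- merge_config(default_config(), user)
  class(cfg) <- "run_config"
  cfg
}

#' Write a configuration to YAML
#'
#' Serializes with enough precision that `load_config(save_config(cfg))`
#' reproduces the configuration.
#'
#' @param cfg a `run_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  # yaml drops names on atomic vectors; promote them to maps
  promote <- function(x) {
    if (is.list(x)) return(lapply(x, promote))
    if (!is.null(names(x)) && length(x) > 1) return(as.list(x))
    x
  }
  yaml::write_yaml(promote(unclass(cfg)), path, precision = 15)
  invisible(path)
}

#' Short reproducibility hash of a configuration
#' @param cfg a `run_config` (any serializable list).
#' @return character scalar.
#' @export
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  # FNV-1a over the serialized bytes; dependency-free content fingerprint
  h <- 2166136261
  for (b in as.integer(charToRaw(s))) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Configuration of the reduced benchmark world
#'
#' A deliberately simplified study system used for desk-scale validation
#' of the learning pipeline: two channels with only the zonal Z and Z2
#' shims active (the dominant inhomogeneity direction), fully decoupled
#' channels, a noise-free receiver, an axis-only sample grid, and short
#' spectra (512 bins at 1 Hz/bin, natural linewidth 6 Hz, Ref = 12 mA per
#' coil with gains of 3 and 2 Hz/mA). Distortions keep the sigma = Ref/3
#' policy.
#'
#' @return a `run_config` describing the reduced world.
#' @export
reduced_world_config <- function() {
  cfg <- default_config()
  cfg$world$grid <- list(diameter_mm = 1, length_mm = 8, n_radial = 1,
                         n_axial = 33)
  cfg$world$shims <- list(coils = c("Z", "Z2"),
                          gains_hz_per_ma = c(Z = 3, Z2 = 2), ref_ma = 12)
  cfg$world$coupling$epsilon <- 0
  cfg$world$L <- 512
  cfg$world$sweep_hz <- 512
  cfg$world$lines$natural_fwhm_hz <- 6
  cfg$preprocess <- list(roi_size = 512, downsample_factor = 1)
  cfg$model <- list(n_filters = 24, kernel = 9, conv_layers = 3, pool = 2,
                    hidden = 192, dropout = 0)
  cfg$train <- list(epochs = 20, lr = 1e-3, batch_size = 48,
                    huber_delta = 1, curriculum_from = 6, curriculum_to = 6,
                    curriculum_increment = 2, curriculum_step_epochs = 25,
                    plateau_factor = 0.5, plateau_patience = 5,
                    eval_entities = 6)
  cfg$dataset$n_samples <- 2000
  cfg
}

#' Train the reduced-world benchmark model
#'
#' Convenience wrapper: builds the reduced world, generates the dataset,
#' and trains the scaled-down model with the reduced-study recipe
#' (training probes use sigma = Ref/2 — a slightly wider spread than the
#' distortions — to increase the observation contrast that identifies the
#' sign of the odd zonal shim).
#'
#' @param n_samples dataset size (default 2000).
#' @param epochs training epochs (default 20).
#' @param seed global seed.
#' @param verbose print epoch progress.
#' @return list with `sp` (spectrometer), `ds` (dataset), `model`.
#' @export
train_reduced_study <- function(n_samples = 2000, epochs = 20, seed = 11,
                                verbose = FALSE) {
  cfg <- reduced_world_config()
  sp <- build_world(cfg)
  ds <- generate_dataset(sp, n_samples, seed = seed)
  pcfg <- preprocess_config(roi_size = 512, downsample_factor = 1,
                            target_norm_bound = 2 * abs(ds$ref))
  mcfg <- pedr_model_config(input_len = 512, in_channels = 2,
                            action_dim = 4, n_filters = 24, kernel = 9,
                            conv_layers = 3, pool = 2, hidden = 192,
                            dropout = 0)
  tcfg <- pedr_train_config(epochs = epochs, lr = 1e-3, batch_size = 48,
                            curriculum_from = 6, curriculum_to = 6,
                            lr_step_epochs = c(13, 17),
                            eval_entities = 6, action_sigma_frac = 1 / 2,
                            augment = NULL)
  model <- train_pedr(ds, sp, mcfg, tcfg, pcfg, seed = seed + 1,
                      verbose = verbose)
  list(sp = sp, ds = ds, model = model)
}

#' Build the virtual world described by a configuration
#'
#' Instantiates grid, per-channel shim bases, coupling matrix, optional
#' residual intrinsic fields, line models and the virtual spectrometer.
#'
#' @param cfg a `run_config`.
#' @return a [virtual_spectrometer()].
#' @export
build_world <- function(cfg = default_config()) {
  w <- cfg$world
  grid <- build_sample_grid(w$grid$diameter_mm, w$grid$length_mm,
                            w$grid$n_radial, w$grid$n_axial)
  coils <- w$shims$coils
  gains <- rep_len(w$shims$gains_hz_per_ma, length(coils))
  basis <- lapply(seq_len(w$m), function(ch)
    build_sh_basis(grid, gains, coils))
  n <- length(coils)
  coupling <- coupling_matrix(w$m, n, w$coupling$epsilon, w$coupling$seed)
  intrinsic <- NULL
  if (w$distortion$z_span_hz > 0 || w$distortion$xy_span_hz > 0)
    intrinsic <- lapply(seq_len(w$m), function(ch) {
      fmap <- sample_intrinsic_distortion(grid, w$distortion$z_span_hz,
                                          w$distortion$xy_span_hz,
                                          seed = w$distortion$seed + ch)
      fmap$channel_id <- ch
      fmap
    })
  lines <- lapply(seq_len(w$m), function(ch)
    line_model(w$lines$positions_hz, w$lines$amplitudes,
               w$lines$natural_fwhm_hz))
  ref <- rep_len(w$shims$ref_ma, w$m * n)
  virtual_spectrometer(grid, basis, coupling, lines, ref,
                       intrinsic = intrinsic, L = w$L,
                       sweep_hz = w$sweep_hz, receiver = w$receiver)
}
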