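#' Draw a random shim distortion vector
#'
#' Each component is Gaussian with mean 0 and standard deviation one third
#' of the corresponding reference shim current, the scale at which the
#' training data is collected.
#'
#' @param ref reference shim currents (mA), length `m*n` channel-major.
#' @param sigma_frac fraction of `ref` used as sigma (default 1/3).
#' @return numeric distortion vector (mA), same length as `ref`.
#' @export
draw_distortion <- function(ref, sigma_frac = 1 / 3) {
  stopifnot(all(is.finite(ref)))
  stats::rnorm(length(ref), 0, abs(ref) * sigma_frac)
}

# deterministic 80/10/10 split: nearest-integer sizes for val/test,
# remainder to train (8799 samples -> 7039/880/880)
split_indices <- function(n_samples, ratios = c(train = 0.8, val = 0.1,
                                                test = 0.1)) {
  n_val <- round(n_samples * ratios[["val"]])
  n_test <- round(n_samples * ratios[["test"]])
  n_train <- n_samples - n_val - n_test
  perm <- sample.int(n_samples)
  split <- character(n_samples)
  split[perm[seq_len(n_train)]] <- "train"
  split[perm[n_train + seq_len(n_val)]] <- "val"
  split[perm[n_train + n_val + seq_len(n_test)]] <- "test"
  factor(split, levels = c("train", "val", "test"))
}

#' Generate a synthetic shimming dataset
#'
#' Emulates the experimental data collection: for each sample a fresh
#' distortion `S` is drawn (Gaussian, sigma = Ref/3 per component), applied
#' to the virtual spectrometer, and the unshimmed spectrum pair `u(0)` is
#' recorded. Samples are assigned to train/val/test splits with ratios
#' 80/10/10 (nearest-integer sizes for val/test, remainder to train),
#' deterministically
#' from the seed. Sequence spectra are *not* stored: training sequences are
#' constructed online (see [build_training_sequence()]), so the dataset
#' holds the unshimmed pairs, the targets and the world parameters.
#'
#' @param sp a [virtual_spectrometer()]; its distortion state is left at the
#'   last sample's `S` and its acquisition counter is not advanced (dataset
#'   synthesis is not metered acquisition).
#' @param n_samples number of samples (>= 10).
#' @param seed integer seed controlling distortions, split, and receiver
#'   noise.
#' @param sigma_frac distortion sigma as a fraction of `ref` (default 1/3).
#' @return object of class `shim_dataset`: list with `spectra` (array
#'   `n_samples x m x L`), `targets` (matrix `n_samples x m*n`), `ref`,
#'   `split`, `L`, `m`, `n`, `sweep_hz`, `sigma_frac`, `seed`.
#' @export
generate_dataset <- function(sp, n_samples, seed = 1, sigma_frac = 1 / 3) {
  stopifnot(inherits(sp, "virtual_spectrometer"))
  if (n_samples < 10) stop("n_samples must be >= 10")
  m <- sp$m; n <- sp$n; L <- sp$L
  with_seed(seed, {
    targets <- t(replicate(n_samples, draw_distortion(sp$ref, sigma_frac)))
    split <- split_indices(n_samples)
    spectra <- array(NA_real_, dim = c(n_samples, m, L))
    chunk <- 512L
    for (lo in seq(1L, n_samples, by = chunk)) {
      hi <- min(lo + chunk - 1L, n_samples)
      eff <- t(targets[lo:hi, , drop = FALSE])     # u(0): effective S - 0
      ch_mats <- acquire_batch(sp, eff)
      for (ch in seq_len(m))
        spectra[lo:hi, ch, ] <- t(ch_mats[[ch]])
    }
  })
  structure(list(spectra = spectra, targets = targets, ref = sp$ref,
                 split = split, L = L, m = m, n = n,
                 sweep_hz = sp$sweep_hz, sigma_frac = sigma_frac,
                 seed = seed),
            class = "shim_dataset")
}

#' @export
print.shim_dataset <- function(x, ...) {
  cat(sprintf("<shim_dataset> %d samples (%s), m=%d channels, n=%d coils, L=%d\n",
              nrow(x$targets),
              paste(table(x$split), collapse = "/"), x$m, x$n, x$L))
  invisible(x)
}

#' Build one training sequence online
#'
#' Constructs the sequence `x = [(u(0), 0), (u(a_1), a_1), ...,
#' (u(a_t), a_t)]` for one stored sample: `t` random actions are drawn
#' fresh (Gaussian offsets from the initial unshimmed state, same sigma
#' policy as the distortions unless overridden) and the corresponding
#' spectrum pairs are synthesized on the fly. The regression target is the
#' sample's stored distortion `S`.
#'
#' @param ds a [generate_dataset()] result.
#' @param sample_idx index of the sample in the dataset.
#' @param t number of random action steps (0 gives just the unshimmed
#'   entity); must not exceed `max_t`.
#' @param sp the virtual spectrometer that generated the dataset.
#' @param sigma_frac sigma policy for the random actions (default: the
#'   dataset's).
#' @param max_t maximum allowed `t` (default 9, i.e. 10 entities).
#' @return object of class `shim_sequence`: list with `spectra` (list of
#'   `t+1` matrices `L x m`), `actions` (matrix `(t+1) x m*n`, first row
#'   zero), `target` (length `m*n`).
#' @export
build_training_sequence <- function(ds, sample_idx, t, sp,
                                    sigma_frac = NULL, max_t = 9) {
  stopifnot(inherits(ds, "shim_dataset"))
  if (t < 0 || t > max_t) stop("t must be in [0, ", max_t, "]")
  if (is.null(sigma_frac)) sigma_frac <- ds$sigma_frac
  S <- ds$targets[sample_idx, ]
  d <- length(S)
  actions <- matrix(0, nrow = t + 1, ncol = d)
  if (t > 0)
    actions[-1, ] <- t(replicate(t, draw_distortion(ds$ref, sigma_frac)))
  spectra <- vector("list", t + 1)
  spectra[[1]] <- t(rbind(ds$spectra[sample_idx, , ]))
  dim(spectra[[1]]) <- c(ds$L, ds$m)
  if (t > 0) {
    eff <- S - t(actions[-1, , drop = FALSE])    # (m*n x t)
    mats <- acquire_batch(sp, eff)
    for (k in seq_len(t))
      spectra[[k + 1]] <- vapply(seq_len(ds$m),
                                 function(ch) mats[[ch]][, k],
                                 numeric(ds$L))
  }
  structure(list(spectra = spectra, actions = actions, target = S),
            class = "shim_sequence")
}

#' Save a shimming dataset to a directory container
#'
#' Layout: `manifest.json` (n_samples, L, m, n, seed, sigma_frac, sweep_hz,
#' split counts), `ref.csv`, `targets.csv`, `split.csv` and one
#' `spectra_ch<k>.csv` matrix per channel (rows = samples). Round-trips are
#' lossless for doubles (values are written at full precision).
#'
#' @param ds a `shim_dataset`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
save_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "shim_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(n_samples = nrow(ds$targets), L = ds$L, m = ds$m,
                   n = ds$n, seed = ds$seed, sigma_frac = ds$sigma_frac,
                   sweep_hz = ds$sweep_hz,
                   split_counts = as.list(table(ds$split)))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  data.table::fwrite(data.table::as.data.table(ds$targets),
                     file.path(path, "targets.csv"))
  data.table::fwrite(data.table::data.table(ref = ds$ref),
                     file.path(path, "ref.csv"))
  data.table::fwrite(data.table::data.table(split = as.character(ds$split)),
                     file.path(path, "split.csv"))
  for (ch in seq_len(ds$m)) {
    mat <- ds$spectra[, ch, ]
    dim(mat) <- c(nrow(ds$targets), ds$L)
    data.table::fwrite(data.table::as.data.table(mat),
                       file.path(path, sprintf("spectra_ch%d.csv", ch)))
  }
  invisible(path)
}

#' Load a shimming dataset from its directory container
#'
#' @param path directory written by [save_dataset()].
#' @return a `shim_dataset`.
#' @export
load_dataset <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path))
    stop("not a dataset container: missing manifest.json in ", path)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  for (key in c("n_samples", "L", "m", "n", "seed", "sigma_frac", "sweep_hz"))
    if (is.null(mf[[key]]))
      stop("corrupt manifest: missing key '", key, "'")
  targets <- as.matrix(data.table::fread(file.path(path, "targets.csv")))
  dimnames(targets) <- NULL
  ref <- data.table::fread(file.path(path, "ref.csv"))$ref
  split <- factor(data.table::fread(file.path(path, "split.csv"))$split,
                  levels = c("train", "val", "test"))
  spectra <- array(NA_real_, dim = c(mf$n_samples, mf$m, mf$L))
  for (ch in seq_len(mf$m)) {
    mat <- as.matrix(data.table::fread(
      file.path(path, sprintf("spectra_ch%d.csv", ch))))
    dimnames(mat) <- NULL
    spectra[, ch, ] <- mat
  }
  structure(list(spectra = spectra, targets = targets, ref = ref,
                 split = split, L = mf$L, m = mf$m, n = mf$n,
                 sweep_hz = mf$sweep_hz, sigma_frac = mf$sigma_frac,
                 seed = mf$seed),
            class = "shim_dataset")
}
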