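#' Preprocessing configuration
#'
#' @param roi_size region-of-interest length in raw bins (default 4096).
#' @param downsample_factor integer block size for mean-downsampling
#'   (default 2, giving model inputs of 2048 bins under the defaults).
#' @param carrier_bin raw bin index the ROI is centred on (default: the
#'   middle of the raw spectrum).
#' @param target_norm_bound per-component scale mapping regression targets
#'   to `[-1, 1]`; default `2 * ref`, chosen so that evaluation-time
#'   distortions up to twice the reference values stay inside the tanh
#'   output range.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(roi_size = 4096, downsample_factor = 2,
                              carrier_bin = NULL, target_norm_bound = NULL) {
  stopifnot(downsample_factor >= 1, roi_size >= 1,
            roi_size %% downsample_factor == 0)
  structure(list(roi_size = as.integer(roi_size),
                 downsample_factor = as.integer(downsample_factor),
                 carrier_bin = carrier_bin,
                 target_norm_bound = target_norm_bound),
            class = "preprocess_config")
}

#' Crop a spectrum to the ROI and downsample
#'
#' Cuts a region of interest of `roi_size` raw bins centred on the carrier
#' bin, then downsamples by averaging adjacent blocks of
#' `downsample_factor` bins. Output length is
#' `roi_size / downsample_factor`.
#'
#' @param spec a `spectrum`, or a numeric vector/matrix (columns = spectra).
#' @param cfg a [preprocess_config()].
#' @return same shape class as the input, cropped and downsampled.
#' @export
crop_and_downsample <- function(spec, cfg = preprocess_config()) {
  if (inherits(spec, "spectrum")) {
    y <- crop_and_downsample(cbind(spec$intensities), cfg)
    ax <- crop_and_downsample(cbind(spec$axis_hz), cfg)
    return(new_spectrum(y[, 1], ax[, 1], channel_id = spec$meta$channel_id,
                        acq_index = spec$meta$acq_index,
                        warn = spec$meta$warn))
  }
  x <- if (is.matrix(spec)) spec else cbind(spec)
  Lraw <- nrow(x)
  if (Lraw < cfg$roi_size)
    stop("raw length ", Lraw, " shorter than roi_size ", cfg$roi_size)
  centre <- if (is.null(cfg$carrier_bin)) (Lraw %/% 2L) else cfg$carrier_bin
  lo <- centre - cfg$roi_size %/% 2L + 1L
  lo <- max(1L, min(lo, Lraw - cfg$roi_size + 1L))
  x <- x[lo:(lo + cfg$roi_size - 1L), , drop = FALSE]
  k <- cfg$downsample_factor
  if (k > 1L) {
    dim(x) <- c(k, cfg$roi_size %/% k * ncol(x))
    x <- matrix(colMeans(x), ncol = if (is.matrix(spec)) ncol(spec) else 1L)
  }
  if (is.matrix(spec)) x else x[, 1]
}

#' Normalize a shimming sequence to the first spectra's intensity scale
#'
#' The first entity's spectrum pair (and the second, when present) defines
#' the scale: let `m0` and `M` be the minimum and maximum intensity over
#' those first (up to) two pairs. Every spectrum of the sequence is mapped
#' through `(y - m0) / (M - m0)`, so the brightest of the first spectra
#' maps to 1 while later spectra keep the same scale and may exceed 1.
#' Scale-equivariant: multiplying all raw spectra by `k > 0` leaves the
#' result unchanged.
#'
#' @param seq a `shim_sequence` (spectra already cropped/downsampled or raw).
#' @return the sequence with normalized spectra; the scale `(m0, M)` is
#'   attached as attribute `"norm"`.
#' @export
normalize_sequence <- function(seq) {
  stopifnot(inherits(seq, "shim_sequence"))
  if (length(seq$spectra) == 0) stop("sequence has no entities")
  head2 <- seq$spectra[seq_len(min(2L, length(seq$spectra)))]
  m0 <- min(vapply(head2, min, numeric(1)))
  M <- max(vapply(head2, max, numeric(1)))
  if (M - m0 <= 0) stop("degenerate sequence: flat first spectra")
  seq$spectra <- lapply(seq$spectra, function(s) (s - m0) / (M - m0))
  attr(seq, "norm") <- c(m0 = m0, M = M)
  seq
}

#' Normalize regression targets to `[-1, 1]`
#'
#' @param y distortion vector (or matrix, rows = cases) in mA.
#' @param bound positive per-component scale; values are divided by it and
#'   clipped to `[-1, 1]`.
#' @return normalized targets.
#' @seealso [denormalize_targets()]
#' @export
normalize_targets <- function(y, bound) {
  stopifnot(all(bound > 0))
  if (is.matrix(y)) {
    out <- sweep(y, 2, bound, "/")
  } else {
    out <- y / bound
  }
  pmin(pmax(out, -1), 1)
}

#' Invert target normalization
#'
#' Exact inverse of [normalize_targets()] for values that were not clipped.
#' @param y_norm normalized targets.
#' @param bound the scale used to normalize.
#' @return targets in mA.
#' @export
denormalize_targets <- function(y_norm, bound) {
  if (is.matrix(y_norm)) sweep(y_norm, 2, bound, "*") else y_norm * bound
}

#' Augmentation configuration
#'
#' Defaults follow the training recipe: uniform circular Z0 shift in
#' `[-4, 4]` bins, uniform label noise of half-width 0.1 on the normalized
#' targets, uniform shim interaction noise of 0.1 (multiplicative, on the
#' normalized actions), first-order phase distortions of +/- 0.5 radians
#' across the ROI, and additive white Gaussian noise at SNR 30.
#'
#' @param z0_shift_range integer half-range of the circular shift (bins).
#' @param label_noise half-width of the uniform target noise.
#' @param interaction_noise half-width of the multiplicative action noise.
#' @param phase1_range half-range of the first-order phase (radians across
#'   the ROI; set `phase1_cycles = TRUE` to interpret as cycles).
#' @param awgn_snr linear peak/noise-sd ratio (Inf disables).
#' @param phase1_cycles interpret `phase1_range` in cycles across the ROI.
#' @return list of class `augment_config`. Setting every range to 0 and
#'   `awgn_snr = Inf` yields the identity transform.
#' @export
augment_config <- function(z0_shift_range = 4, label_noise = 0.1,
                           interaction_noise = 0.1, phase1_range = 0.5,
                           awgn_snr = 30, phase1_cycles = FALSE) {
  structure(list(z0_shift_range = z0_shift_range, label_noise = label_noise,
                 interaction_noise = interaction_noise,
                 phase1_range = phase1_range, awgn_snr = awgn_snr,
                 phase1_cycles = phase1_cycles),
            class = "augment_config")
}

circ_shift <- function(y, s) {
  n <- length(y)
  s <- ((s %% n) + n) %% n
  if (s == 0) y else c(y[(n - s + 1):n], y[1:(n - s)])
}

#' Augment a normalized training sequence
#'
#' Applies, independently per call: one integer circular shift common to
#' all spectra of the sequence; uniform additive noise on the normalized
#' target; multiplicative uniform perturbation of the (normalized) actions;
#' a random first-order phase distortion; and AWGN at the configured SNR.
#' Never alters the sequence length or the zero first action.
#'
#' @param seq a normalized `shim_sequence` whose `target_norm` and
#'   `actions_norm` fields are set (see [prepare_sequence()]), or a plain
#'   normalized sequence (then only spectra and target_norm/actions_norm
#'   present are touched).
#' @param cfg an [augment_config()].
#' @return the augmented sequence.
#' @export
augment_sequence <- function(seq, cfg = augment_config()) {
  stopifnot(inherits(seq, "shim_sequence"))
  if (cfg$z0_shift_range > 0) {
    s <- sample.int(2L * cfg$z0_shift_range + 1L, 1L) -
      cfg$z0_shift_range - 1L
    seq$spectra <- lapply(seq$spectra, function(m)
      apply(m, 2, circ_shift, s = s))
  }
  if (cfg$phase1_range > 0) {
    p1 <- stats::runif(1, -cfg$phase1_range, cfg$phase1_range)
    if (cfg$phase1_cycles) p1 <- 2 * pi * p1
    nL <- nrow(seq$spectra[[1]])
    ramp <- p1 * (seq_len(nL) - 1) / (nL - 1) - p1 / 2
    rot <- exp(1i * ramp)
    seq$spectra <- lapply(seq$spectra, function(m)
      apply(m, 2, function(col) Re(analytic_signal(col) * rot)))
  }
  if (is.finite(cfg$awgn_snr)) {
    seq$spectra <- lapply(seq$spectra, function(m) {
      sds <- apply(abs(m), 2, max) / cfg$awgn_snr
      m + matrix(stats::rnorm(length(m)), nrow(m)) *
        rep(sds, each = nrow(m))
    })
  }
  if (!is.null(seq$target_norm) && cfg$label_noise > 0) {
    seq$target_norm <- seq$target_norm +
      stats::runif(length(seq$target_norm), -cfg$label_noise,
                   cfg$label_noise)
  }
  if (!is.null(seq$actions_norm) && cfg$interaction_noise > 0 &&
      nrow(seq$actions_norm) > 1) {
    pert <- matrix(stats::runif(length(seq$actions_norm[-1, ]),
                                1 - cfg$interaction_noise,
                                1 + cfg$interaction_noise),
                   nrow = nrow(seq$actions_norm) - 1)
    seq$actions_norm[-1, ] <- seq$actions_norm[-1, , drop = FALSE] * pert
  }
  seq
}

#' Prepare a raw sequence for the model
#'
#' Convenience pipeline: crop/downsample every spectrum, normalize the
#' sequence intensities, and normalize the actions and target by
#' `target_norm_bound`.
#'
#' @param seq a raw `shim_sequence`.
#' @param cfg a [preprocess_config()] with `target_norm_bound` set.
#' @return the sequence with fields `spectra` (normalized, model length),
#'   `actions_norm`, `target_norm` added.
#' @export
prepare_sequence <- function(seq, cfg) {
  stopifnot(inherits(cfg, "preprocess_config"),
            !is.null(cfg$target_norm_bound))
  seq$spectra <- lapply(seq$spectra, crop_and_downsample, cfg = cfg)
  seq <- normalize_sequence(seq)
  seq$actions_norm <- normalize_targets(seq$actions, cfg$target_norm_bound)
  seq$target_norm <- normalize_targets(rbind(seq$target),
                                       cfg$target_norm_bound)[1, ]
  seq
}
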