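#' Describe the spectral lines of a channel's sample
#'
#' A channel's sample is parameterized as a list of resonance lines
#' (position in Hz on the channel's offset axis, relative amplitude) plus a
#' natural Lorentzian linewidth. Lineshapes are unit-area, so a line's
#' amplitude equals its integrated intensity.
#'
#' @param positions_hz line positions (Hz).
#' @param amplitudes relative line amplitudes (> 0), recycled to match.
#' @param natural_fwhm_hz natural (homogeneous-field) Lorentzian FWHM in Hz.
#' @return object of class `line_model`.
#' @export
line_model <- function(positions_hz = 0, amplitudes = 1,
                       natural_fwhm_hz = 10) {
  amplitudes <- rep_len(amplitudes, length(positions_hz))
  if (any(amplitudes <= 0)) stop("line amplitudes must be > 0")
  if (natural_fwhm_hz <= 0) stop("natural_fwhm_hz must be > 0")
  structure(list(positions_hz = as.numeric(positions_hz),
                 amplitudes = as.numeric(amplitudes),
                 natural_fwhm_hz = natural_fwhm_hz),
            class = "line_model")
}

# unit-area Lorentzian of FWHM gamma centred at 0
lorentzian <- function(f, gamma) {
  hw <- gamma / 2
  (hw / pi) / (f * f + hw * hw)
}

#' Construct a spectrum object
#' @param intensities real intensity vector.
#' @param axis_hz frequency axis (Hz), strictly monotone, same length.
#' @param channel_id,acq_index metadata.
#' @param warn optional character warning flags recorded in `meta`.
#' @return object of class `spectrum`.
#' @export
new_spectrum <- function(intensities, axis_hz, channel_id = NA_integer_,
                         acq_index = NA_integer_, warn = character()) {
  stopifnot(length(intensities) == length(axis_hz))
  structure(list(intensities = as.numeric(intensities),
                 axis_hz = as.numeric(axis_hz),
                 meta = list(channel_id = channel_id, acq_index = acq_index,
                             warn = warn)),
            class = "spectrum")
}

spectrum_axis <- function(L, sweep_hz) {
  seq(-sweep_hz / 2, sweep_hz / 2, length.out = L)
}

#' Synthesize a 1D absorption spectrum from a field map
#'
#' Forward model of the virtual probe: every grid point contributes, with
#' its quadrature weight, a unit-area Lorentzian of the natural linewidth
#' shifted by the point's field offset; lines enter with their amplitudes.
#' The integrated intensity (sum times bin width) therefore equals the total
#' line amplitude whenever the sweep contains the lineshape.
#'
#' @param field a `field_map` (per-grid-point offsets, Hz).
#' @param lines a [line_model()].
#' @param weights quadrature weights matching the field map (from the grid).
#' @param L number of spectral bins (>= 64).
#' @param sweep_hz spectral width (Hz); the axis runs symmetrically about 0.
#' @return a `spectrum`. If the sweep fails to contain ~99% of the
#'   spectral mass, a `"sweep_too_narrow"` flag is recorded in `meta$warn`.
#' @export
synthesize_spectrum <- function(field, lines, weights, L = 8192,
                                sweep_hz = 8192) {
  if (L < 64) stop("L must be >= 64")
  stopifnot(inherits(field, "field_map"), inherits(lines, "line_model"))
  if (length(weights) != length(field$offsets))
    stop("weights length must match field map")
  f <- spectrum_axis(L, sweep_hz)
  y <- numeric(L)
  for (p in seq_along(field$offsets)) {
    shift <- field$offsets[p]
    for (k in seq_along(lines$positions_hz)) {
      y <- y + weights[p] * lines$amplitudes[k] *
        lorentzian(f - lines$positions_hz[k] - shift, lines$natural_fwhm_hz)
    }
  }
  warn <- character()
  area <- sum(y) * (sweep_hz / (L - 1))
  if (area < 0.99 * sum(lines$amplitudes)) warn <- "sweep_too_narrow"
  new_spectrum(y, f, channel_id = field$channel_id, warn = warn)
}

# vectorized batch synthesis: offsets is (n_points x B); returns (L x B)
# intensity matrix. Used by the dataset generator and training loop.
synthesize_batch <- function(offsets, lines, weights, L, sweep_hz) {
  f <- spectrum_axis(L, sweep_hz)
  Y <- matrix(0, L, ncol(offsets))
  for (k in seq_along(lines$positions_hz)) {
    Y <- Y + cpp_lorentz_batch(f, offsets + lines$positions_hz[k],
                               weights, lines$amplitudes[k],
                               lines$natural_fwhm_hz)
  }
  Y
}

# analytic signal via FFT (positive-frequency doubling)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Apply receiver effects to a spectrum
#'
#' Models the virtual receiver chain: linear inter-channel RF leakage,
#' a circular frequency shift (z0 drift in bins), a first-order phase error
#' applied in the complex domain via the analytic signal, and additive white
#' Gaussian noise scaled so that peak amplitude over noise standard
#' deviation equals `snr`.
#'
#' @param spec input `spectrum`.
#' @param snr linear peak-to-noise-sd ratio; `Inf` disables noise. Set
#'   `snr_db = TRUE` to interpret the value in dB instead.
#' @param phase1 first-order phase in radians across the spectrum (linear
#'   ramp from `-phase1/2` at the first bin to `+phase1/2` at the last).
#' @param z0_shift integer circular shift in bins.
#' @param leak_from spectrum leaking in from the other channel (or NULL).
#' @param leak_coeff leakage fraction in `[0, 1)`; output is
#'   `(1 - leak_coeff) * spec + leak_coeff * leak_from`.
#' @param snr_db interpret `snr` in decibels (default FALSE, linear).
#' @return a `spectrum` with the effects applied.
#' @export
apply_receiver_effects <- function(spec, snr = Inf, phase1 = 0, z0_shift = 0,
                                   leak_from = NULL, leak_coeff = 0,
                                   snr_db = FALSE) {
  stopifnot(inherits(spec, "spectrum"), snr > 0,
            leak_coeff >= 0, leak_coeff < 1)
  y <- spec$intensities
  if (leak_coeff > 0) {
    if (is.null(leak_from)) stop("leak_coeff > 0 requires leak_from")
    y <- (1 - leak_coeff) * y + leak_coeff * leak_from$intensities
  }
  if (z0_shift != 0) {
    n <- length(y)
    s <- ((z0_shift %% n) + n) %% n
    if (s != 0) y <- c(y[(n - s + 1):n], y[1:(n - s)])
  }
  if (phase1 != 0) {
    n <- length(y)
    ramp <- phase1 * (seq_len(n) - 1) / (n - 1) - phase1 / 2
    y <- Re(analytic_signal(y) * exp(1i * ramp))
  }
  if (is.finite(snr)) {
    snr_lin <- if (snr_db) 10^(snr / 20) else snr
    sd <- max(abs(y)) / snr_lin
    y <- y + stats::rnorm(length(y), 0, sd)
  }
  new_spectrum(y, spec$axis_hz, channel_id = spec$meta$channel_id,
               acq_index = spec$meta$acq_index, warn = spec$meta$warn)
}

#' Create a virtual two-channel spectrometer
#'
#' Bundles the shim world (grid, per-channel shim bases, coupling matrix,
#' optional residual intrinsic fields, line models) with receiver settings,
#' mutable shim state and an acquisition counter. The reference shim state
#' absorbs the manually shimmed baseline: the field presented to the sample
#' is generated by the effective distortion currents `S - a`, so the action
#' `a = S` restores reference homogeneity exactly.
#'
#' @param grid sample grid.
#' @param basis list of per-channel `shim_basis` objects (length m).
#' @param coupling coupling matrix `(m*n) x (m*n)`.
#' @param lines list of per-channel [line_model()]s.
#' @param ref reference shim currents (mA), length `m*n` channel-major;
#'   their magnitudes set the sigma = Ref/3 distortion scale.
#' @param intrinsic optional list of per-channel residual `field_map`s.
#' @param L,sweep_hz raw spectrum length and sweep width.
#' @param receiver list of receiver settings: `snr` (linear, Inf = off),
#'   `snr_db`, `phase1`, `z0_drift_per_acq` (bins), `leak_coeff`.
#' @return an environment of class `virtual_spectrometer`.
#' @export
virtual_spectrometer <- function(grid, basis, coupling, lines, ref,
                                 intrinsic = NULL, L = 8192, sweep_hz = 8192,
                                 receiver = list()) {
  m <- length(basis)
  n <- length(basis[[1]]$coil_names)
  if (length(lines) != m) stop("need one line model per channel")
  if (length(ref) != m * n) stop("ref must have length m*n = ", m * n)
  rec <- utils::modifyList(
    list(snr = Inf, snr_db = FALSE, phase1 = 0,
         z0_drift_per_acq = 0, leak_coeff = 0), receiver)
  sp <- new.env(parent = emptyenv())
  sp$grid <- grid; sp$basis <- basis; sp$coupling <- coupling
  sp$lines <- lines; sp$ref <- as.numeric(ref); sp$intrinsic <- intrinsic
  sp$L <- L; sp$sweep_hz <- sweep_hz; sp$receiver <- rec
  sp$m <- m; sp$n <- n
  sp$S <- numeric(m * n)          # applied distortion (mA)
  sp$acquisitions <- 0L
  class(sp) <- "virtual_spectrometer"
  sp
}

#' Apply a shim distortion to the spectrometer
#' @param sp a [virtual_spectrometer()].
#' @param S distortion currents (mA), length `m*n`.
#' @export
set_distortion <- function(sp, S) {
  stopifnot(inherits(sp, "virtual_spectrometer"))
  if (length(S) != sp$m * sp$n) stop("S must have length m*n")
  sp$S <- as.numeric(S)
  invisible(sp)
}

#' Number of acquisitions consumed so far
#' @param sp a [virtual_spectrometer()].
#' @export
acquisition_count <- function(sp) sp$acquisitions

#' Reset the acquisition counter
#' @param sp a [virtual_spectrometer()].
#' @export
reset_acquisitions <- function(sp) { sp$acquisitions <- 0L; invisible(sp) }

#' Acquire one spectrum pair under an action
#'
#' Synthesizes one spectrum per channel from the total field generated by
#' the effective distortion `S - a` (so `a = S` is the perfect correction and
#' `a = 0` gives the unshimmed pair), applies receiver effects, and
#' increments the acquisition counter by exactly 1 (the cost unit used in
#' every baseline comparison).
#'
#' @param sp a [virtual_spectrometer()].
#' @param a action currents (mA), length `m*n`, offsets w.r.t. the initial
#'   state; default zero.
#' @return list of `m` `spectrum` objects.
#' @export
acquire <- function(sp, a = numeric(sp$m * sp$n)) {
  stopifnot(inherits(sp, "virtual_spectrometer"))
  if (length(a) != sp$m * sp$n) stop("action must have length m*n")
  fields <- total_field(sp$basis, sp$S - a, sp$coupling, sp$intrinsic)
  sp$acquisitions <- sp$acquisitions + 1L
  raw <- lapply(seq_len(sp$m), function(ch)
    synthesize_spectrum(fields[[ch]], sp$lines[[ch]], sp$grid$weights,
                        sp$L, sp$sweep_hz))
  rec <- sp$receiver
  drift <- round(rec$z0_drift_per_acq * sp$acquisitions)
  out <- lapply(seq_len(sp$m), function(ch) {
    other <- if (sp$m > 1) raw[[if (ch == 1) 2 else 1]] else NULL
    s <- apply_receiver_effects(raw[[ch]], snr = rec$snr,
                                phase1 = rec$phase1, z0_shift = drift,
                                leak_from = other,
                                leak_coeff = rec$leak_coeff,
                                snr_db = rec$snr_db)
    s$meta$acq_index <- sp$acquisitions
    s
  })
  out
}

# batch analogue of acquire() without counter semantics: given a matrix of
# effective distortions (m*n x B), return list over channels of (L x B)
# intensity matrices. Receiver noise is applied when snr is finite.
acquire_batch <- function(sp, eff, noise = TRUE) {
  B <- ncol(eff)
  amps <- sp$coupling %*% eff                    # (m*n x B)
  out <- vector("list", sp$m)
  for (ch in seq_len(sp$m)) {
    idx <- (ch - 1) * sp$n + seq_len(sp$n)
    offs <- sp$basis[[ch]]$profiles %*% amps[idx, , drop = FALSE]
    if (!is.null(sp$intrinsic) && !is.null(sp$intrinsic[[ch]]))
      offs <- offs + sp$intrinsic[[ch]]$offsets
    out[[ch]] <- synthesize_batch(offs, sp$lines[[ch]], sp$grid$weights,
                                  sp$L, sp$sweep_hz)
  }
  if (sp$m > 1 && sp$receiver$leak_coeff > 0) {
    lc <- sp$receiver$leak_coeff
    mixed <- out
    for (ch in seq_len(sp$m)) {
      other <- if (ch == 1) 2 else 1
      mixed[[ch]] <- (1 - lc) * out[[ch]] + lc * out[[other]]
    }
    out <- mixed
  }
  if (noise && is.finite(sp$receiver$snr)) {
    snr_lin <- if (sp$receiver$snr_db) 10^(sp$receiver$snr / 20)
               else sp$receiver$snr
    for (ch in seq_len(sp$m)) {
      sds <- apply(abs(out[[ch]]), 2, max) / snr_lin
      out[[ch]] <- out[[ch]] +
        matrix(stats::rnorm(length(out[[ch]])), nrow(out[[ch]])) *
        rep(sds, each = nrow(out[[ch]]))
    }
  }
  out
}
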