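#' Full width at half maximum of a spectral peak
#'
#' Default estimator: locate the global maximum, estimate the baseline noise
#' from the outer 10% of bins, and find the half-maximum crossings on both
#' sides of the peak by linear interpolation. If the peak shows splitting
#' (a second local maximum above 50% of the global maximum within the fit
#' window), a pseudo-Voigt profile (Gaussian/Lorentzian mixture with a
#' common width) is fitted and the FWHM of the fitted curve is measured
#' numerically at half maximum.
#'
#' @param spec a `spectrum`, or a numeric intensity vector (then `axis_hz`
#'   must be given).
#' @param axis_hz frequency axis when `spec` is a bare vector.
#' @param window_fwhm_mult half-width of the splitting-detection / fit
#'   window, as a multiple of the crossing-based FWHM (default 10).
#' @return the linewidth in Hz. Attribute `"method"` records whether the
#'   crossing estimator (`"halfmax"`) or the Voigt fit (`"voigt"`) was used.
#' @export
fwhm <- function(spec, axis_hz = NULL, window_fwhm_mult = 10) {
  if (inherits(spec, "spectrum")) {
    y <- spec$intensities; f <- spec$axis_hz
  } else {
    y <- as.numeric(spec); f <- axis_hz
    if (is.null(f)) stop("axis_hz required for a bare intensity vector")
  }
  n <- length(y)
  edge <- max(8L, floor(0.05 * n))
  noise_sd <- stats::sd(c(y[seq_len(edge)], y[(n - edge + 1):n]))
  base <- stats::median(c(y[seq_len(edge)], y[(n - edge + 1):n]))
  ipk <- which.max(y)
  pk <- y[ipk] - base
  if (!is.finite(pk) || pk <= 0 ||
      (is.finite(noise_sd) && noise_sd > 0 && pk < 5 * noise_sd))
    stop("no detectable peak above the noise floor")
  half <- base + pk / 2

  cross <- function(side) {
    idx <- if (side < 0) seq(ipk, 1L) else seq(ipk, n)
    below <- which(y[idx] < half)
    if (length(below) == 0) return(NA_real_)
    j <- idx[below[1]]; jprev <- j - side  # last index still above half
    # linear interpolation between (jprev, j)
    frac <- (y[jprev] - half) / (y[jprev] - y[j])
    f[jprev] + frac * (f[j] - f[jprev])
  }
  left <- cross(-1L); right <- cross(+1L)
  if (is.na(left) || is.na(right))
    stop("half-maximum not bracketed inside the spectrum")
  w_halfmax <- abs(right - left)

  # splitting heuristic: a second local maximum >= 50% of the peak inside
  # the fit window triggers the Voigt fit
  bin <- abs(f[2] - f[1])
  win <- which(abs(f - f[ipk]) <= window_fwhm_mult * w_halfmax)
  yw <- y[win]
  locmax <- which(diff(sign(diff(yw))) == -2) + 1L
  big <- locmax[(yw[locmax] - base) >= 0.5 * pk]
  split <- length(big) >= 2
  if (!split)
    return(structure(w_halfmax, method = "halfmax"))

  fit <- try(fit_pseudo_voigt(f[win], yw, centre = f[ipk],
                              width0 = w_halfmax, base0 = base), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(structure(w_halfmax, method = "halfmax"))
  # numerical half-max width of the fitted curve on a fine grid
  ff <- seq(min(f[win]), max(f[win]), length.out = 20000L)
  yy <- pseudo_voigt(ff, fit$x0, fit$w, fit$eta) * fit$A + fit$b
  hm <- fit$b + (max(yy) - fit$b) / 2
  above <- range(which(yy >= hm))
  structure((ff[above[2]] - ff[above[1]]),
            method = "voigt", fit = fit)
}

# pseudo-Voigt profile with peak height 1: eta * Lorentzian + (1-eta) *
# Gaussian, both of FWHM w, centred at x0
pseudo_voigt <- function(x, x0, w, eta) {
  hw <- w / 2
  lor <- hw^2 / ((x - x0)^2 + hw^2)
  gau <- exp(-4 * log(2) * (x - x0)^2 / w^2)
  eta * lor + (1 - eta) * gau
}

fit_pseudo_voigt <- function(x, y, centre, width0, base0) {
  A0 <- max(y) - base0
  dat <- data.frame(x = x, y = y)
  fit <- minpack.lm::nlsLM(
    y ~ A * pseudo_voigt(x, x0, w, eta) + b,
    data = dat,
    start = list(A = A0, x0 = centre, w = width0, eta = 0.5, b = base0),
    lower = c(A = 0, x0 = min(x), w = .Machine$double.eps, eta = 0, b = -Inf),
    upper = c(A = Inf, x0 = max(x), w = diff(range(x)), eta = 1, b = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  as.list(stats::coef(fit))
}

#' Direction ratio between a prediction and a target
#'
#' Fraction of shim components whose predicted sign matches the target's.
#' Convention for zeros: `sign(0)` matches only `sign(0)`, i.e. a zero
#' prediction counts as a non-match unless the target component is exactly
#' zero.
#'
#' @param pred,target numeric vectors of equal length (one entry per shim
#'   component), or matrices with one row per case.
#' @return DiR in `[0, 1]`.
#' @export
direction_ratio <- function(pred, target) {
  if (length(pred) != length(target))
    stop("pred and target must have equal length")
  mean(sign(pred) == sign(target))
}

#' Success rate over shimming episodes
#'
#' An episode is a success when the final spectral peak intensity exceeds
#' the initial one on *both* channels; SR is the fraction of successful
#' episodes.
#'
#' @param episodes list of `episode_result` objects (see
#'   [run_pedr_episode()]), each with `initial_peak` and `final_peak`
#'   per-channel vectors.
#' @return SR in `[0, 1]`.
#' @export
success_rate <- function(episodes) {
  if (inherits(episodes, "episode_result")) episodes <- list(episodes)
  mean(vapply(episodes, function(e)
    all(e$final_peak > e$initial_peak), logical(1)))
}
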