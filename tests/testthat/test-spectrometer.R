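test_that("synthesizer reproduces the Lorentzian width, shifts and area", {
  g <- build_sample_grid(1, 8, 1, 3)
  lm0 <- line_model(0, 1, natural_fwhm_hz = 5)
  fm <- parashim:::zero_field(g, 1)
  s <- synthesize_spectrum(fm, lm0, g$weights, L = 4096, sweep_hz = 4096)
  bin <- s$axis_hz[2] - s$axis_hz[1]
  expect_lt(abs(as.numeric(fwhm(s)) - 5), bin)
  # area equals the total line amplitude when the sweep contains the line
  expect_equal(sum(s$intensities) * bin, 1, tolerance = 1e-3)
  expect_length(s$meta$warn, 0)
  # uniform +50 Hz offset moves the peak by +50 Hz (within one bin)
  fm$offsets <- fm$offsets + 50
  s2 <- synthesize_spectrum(fm, lm0, g$weights, L = 4096, sweep_hz = 4096)
  expect_lt(abs(s2$axis_hz[which.max(s2$intensities)] - 50), bin)
  # too-narrow sweep is flagged
  s3 <- synthesize_spectrum(fm, lm0, g$weights, L = 64, sweep_hz = 80)
  expect_true("sweep_too_narrow" %in% s3$meta$warn)
})

test_that("a linear z-gradient gives the box-convolved Lorentzian width", {
  # 1-D uniform grid spanning 200 Hz: lineshape = box(200) (x) Lorentzian(5)
  n <- 401
  g <- build_sample_grid(1, 8, 1, n)
  fm <- parashim:::zero_field(g, 1)
  fm$offsets <- seq(-100, 100, length.out = n)
  lm0 <- line_model(0, 1, natural_fwhm_hz = 5)
  s <- synthesize_spectrum(fm, lm0, g$weights, L = 8192, sweep_hz = 4096)
  # brute-force convolution oracle on a fine grid
  f <- seq(-2048, 2048, length.out = 8192)
  lor <- (2.5 / pi) / (f^2 + 2.5^2)
  box <- as.numeric(abs(f) <= 100); box <- box / sum(box)
  conv <- stats::convolve(lor, rev(box), type = "open")
  fc <- seq(2 * min(f), 2 * max(f), length.out = length(conv))
  w_oracle <- as.numeric(fwhm(conv, axis_hz = fc))
  expect_equal(as.numeric(fwhm(s)), w_oracle, tolerance = 0.02)
})

test_that("batch synthesizer equals the naive double-loop reference", {
  g <- build_sample_grid(1, 8, 4, 4)        # 16-point grid
  lm0 <- line_model(c(-30, 40), c(1, 0.5), natural_fwhm_hz = 7)
  set.seed(3)
  offs <- matrix(rnorm(16 * 3, 0, 40), 16, 3)
  Y <- parashim:::synthesize_batch(offs, lm0, g$weights, 512, 512)
  for (j in 1:3) {
    ref <- naive_synthesize(offs[, j], lm0, g$weights, 512, 512)
    expect_equal(Y[, j], ref, tolerance = 1e-10)
  }
})

test_that("receiver effects: identity, leakage mixing and SNR scaling", {
  g <- build_sample_grid(1, 8, 1, 3)
  lm0 <- line_model(0, 1, 5)
  s <- synthesize_spectrum(parashim:::zero_field(g, 1), lm0, g$weights,
                           L = 2048, sweep_hz = 2048)
  expect_equal(apply_receiver_effects(s, snr = Inf)$intensities,
               s$intensities)
  # linear mixing: a distinct leak line appears at leak_coeff x amplitude
  fm2 <- parashim:::zero_field(g, 2); fm2$offsets <- fm2$offsets + 400
  s_leak <- synthesize_spectrum(fm2, lm0, g$weights, 2048, 2048)
  mixed <- apply_receiver_effects(s, snr = Inf, leak_from = s_leak,
                                  leak_coeff = 0.2)
  i400 <- which.min(abs(s$axis_hz - 400))
  expect_equal(mixed$intensities[i400],
               0.8 * s$intensities[i400] + 0.2 * s_leak$intensities[i400],
               tolerance = 1e-12)
  # circular shift moves the peak by the stated number of bins
  shifted <- apply_receiver_effects(s, snr = Inf, z0_shift = 7)
  expect_equal(which.max(shifted$intensities),
               which.max(s$intensities) + 7)
  # AWGN scaled to peak/sd = snr, checked on noise-only bins
  set.seed(11)
  flat <- new_spectrum(c(rep(0, 9000), 100, rep(0, 1000)),
                       seq_len(10001))
  noisy <- apply_receiver_effects(flat, snr = 30)
  sd_emp <- stats::sd(noisy$intensities[1:8000])
  expect_equal(sd_emp, 100 / 30, tolerance = 0.05 * 100 / 30)
  # dB interpretation: snr_db = 20*log10(ratio)
  set.seed(12)
  noisy_db <- apply_receiver_effects(flat, snr = 20 * log10(30),
                                     snr_db = TRUE)
  expect_equal(stats::sd(noisy_db$intensities[1:8000]), 100 / 30,
               tolerance = 0.05 * 100 / 30)
})

test_that("acquire: perfect correction, unshimmed pair, counting", {
  sp <- tiny_world(L = 1024)
  S <- c(3, -2, 5, 1, -4, 2, -1, 2, -6, 3, 1, -2)
  set_distortion(sp, S)
  reset_acquisitions(sp)
  # a = S nulls the distortion: natural linewidth on both channels
  specs <- acquire(sp, S)
  bin <- specs[[1]]$axis_hz[2] - specs[[1]]$axis_hz[1]
  for (ch in 1:2)
    expect_lt(abs(as.numeric(fwhm(specs[[ch]])) - 8), bin)
  expect_equal(acquisition_count(sp), 1L)
  # a = 0 gives the unshimmed pair, broader than reference
  u0 <- acquire(sp)
  expect_equal(acquisition_count(sp), 2L)
  expect_gt(as.numeric(fwhm(u0[[1]])), as.numeric(fwhm(specs[[1]])))
  # determinism (noise-free world): identical repeat, counter +2
  a <- rep(0.5, 12)
  s1 <- acquire(sp, a); s2 <- acquire(sp, a)
  expect_identical(s1[[1]]$intensities, s2[[1]]$intensities)
  expect_equal(acquisition_count(sp), 4L)
  expect_error(acquire(sp, numeric(5)), "length")
})

test_that("FWHM never falls below the homogeneous value on zonal shims", {
  sp <- tiny_world(L = 1024)
  set_distortion(sp, numeric(12))
  w0 <- as.numeric(fwhm(acquire(sp)[[1]]))
  for (coil in c("Z", "Z2", "Z3", "Z4")) {
    j <- match(coil, SHIM_COILS)
    for (amp in c(2, 5, 9)) {
      S <- numeric(12); S[j] <- amp
      set_distortion(sp, S)
      expect_gte(as.numeric(fwhm(acquire(sp)[[1]])), w0 - 1e-9)
    }
  }
})
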