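# Small worlds shared across tests, built in code.

# tiny full world: 2 channels x 6 coils, short spectra, odd axial count so
# the grid contains z = 0
tiny_world <- function(L = 1024, snr = Inf, epsilon = 0.1,
                       natural_fwhm = 8, n_radial = 5, n_axial = 33) {
  cfg <- default_config()
  cfg$world$grid <- list(diameter_mm = 1, length_mm = 8,
                         n_radial = n_radial, n_axial = n_axial)
  cfg$world$L <- L
  cfg$world$sweep_hz <- L           # 1 Hz per bin
  cfg$world$lines$natural_fwhm_hz <- natural_fwhm
  cfg$world$coupling$epsilon <- epsilon
  cfg$world$receiver$snr <- snr
  build_world(cfg)
}

# the reduced 2-shim study world used by the learning tests
reduced_world <- function() build_world(reduced_world_config())

# memoised heavy computations for the acceptance suite (trained models);
# built on first use so only the tests that need them pay for them
.study_cache <- new.env(parent = emptyenv())

get_reduced_study <- function(n_samples = 2000) {
  key <- paste0("n", n_samples)
  if (is.null(.study_cache[[key]]))
    .study_cache[[key]] <- train_reduced_study(n_samples, 20, seed = 11)
  .study_cache[[key]]
}

# naive R reference implementation of the spectrum forward model (double
# loop over grid points and lines); the oracle for the synthesizer
naive_synthesize <- function(offsets, lines, weights, L, sweep_hz) {
  f <- seq(-sweep_hz / 2, sweep_hz / 2, length.out = L)
  y <- numeric(L)
  hw <- lines$natural_fwhm_hz / 2
  for (p in seq_along(offsets)) {
    for (k in seq_along(lines$positions_hz)) {
      d <- f - lines$positions_hz[k] - offsets[p]
      y <- y + weights[p] * lines$amplitudes[k] * (hw / pi) / (d^2 + hw^2)
    }
  }
  y
}
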