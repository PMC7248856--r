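# shared fixtures: small grids and toy spectra built in code

# fingerprint-region config: fast to generate, covers every band the ratio
# and LDA features need
fp_config <- function(seed = 1, noise_sd = 2e-4) {
  generator_config(grid_high = 1800, grid_low = 650, grid_step = 2,
                   noise_sd = noise_sd, seed = seed)
}

toy_spectrum <- function(absorbance, high = 1800, step = 2, ...) {
  wn <- seq(high, by = -step, length.out = length(absorbance))
  spectrum(wn, absorbance, sample_meta(..., oil_type = "CAO", sample_id = "toy"))
}

# single pseudo-Voigt-free synthetic: flat + one triangular peak
triangle_spectrum <- function(center, apex = 1, width = 10, high = 1800,
                              low = 650, step = 1) {
  wn <- seq(high, low, by = -step)
  ab <- pmax(0, apex * (1 - abs(wn - center) / width))
  spectrum(wn, ab)
}

expect_spectra_equal <- function(a, b, tol = 0) {
  if (tol == 0) expect_identical(a$absorbance, b$absorbance)
  else expect_equal(a$absorbance, b$absorbance, tolerance = tol)
  expect_identical(a$wavenumbers, b$wavenumbers)
}
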