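test_that("savitzky-golay smoothing reproduces polynomials exactly", {
  wn <- seq(1800, 650, by = -2)
  poly2 <- 1e-6 * wn^2 - 2e-3 * wn + 0.5
  s <- spectrum(wn, poly2)
  sm <- savgol_smooth(s, window = 11, polyorder = 2)
  expect_equal(sm$absorbance, poly2, tolerance = 1e-9)
  expect_identical(sm$wavenumbers, wn)

  expect_error(savgol_smooth(s, window = 1), "odd integer >= 3")
  expect_error(savgol_smooth(s, window = 10), "odd")
  expect_error(savgol_smooth(toy_spectrum(rep(0.1, 5)), window = 11), "shorter")
})

test_that("smoothing attenuates white noise by the coefficient norm", {
  set.seed(1)
  n <- 4000
  noise <- rnorm(n)
  s <- spectrum(seq(1800, by = -0.25, length.out = n), noise)
  sm <- savgol_smooth(s, window = 11, polyorder = 2)
  # independent oracle: central-row SG coefficients give the exact variance
  # transfer factor sum(c^2) for an interior point
  coefs <- signal::sgolay(p = 2, n = 11)[6, ]
  factor_expected <- sum(coefs^2)
  interior <- 6:(n - 5)
  expect_equal(var(sm$absorbance[interior]) / var(noise),
               factor_expected, tolerance = 0.05)
})

test_that("first derivative is exact on low-order polynomials", {
  wn <- seq(1800, 650, by = -2)
  a <- 3.2e-4
  ramp <- a * wn + 0.05
  d <- first_derivative(spectrum(wn, ramp), window = 11, polyorder = 3)
  expect_equal(d$absorbance, rep(a, length(wn)), tolerance = 1e-9)

  flat <- first_derivative(spectrum(wn, rep(0.3, length(wn))))
  expect_equal(flat$absorbance, rep(0, length(wn)), tolerance = 1e-12)
})

test_that("first derivative matches the analytic derivative of a sine", {
  wn <- seq(1800, 650, by = -2)
  s <- spectrum(wn, sin(wn / 50))
  d <- first_derivative(s, window = 11, polyorder = 3)
  interior <- 10:(length(wn) - 10)
  expect_lt(max(abs(d$absorbance[interior] - cos(wn[interior] / 50) / 50)), 1e-3)
})

test_that("derivative kills constant baselines and both operators are linear", {
  cfg <- fp_config(noise_sd = 0)
  lib <- build_endmember_library(1)
  s <- synth_spectrum(lib$CAO, cfg, "CAO-1", 1)
  shifted <- spectrum(s$wavenumbers, s$absorbance + 0.07, s$meta)

  d1 <- first_derivative(s)
  d2 <- first_derivative(shifted)
  expect_equal(d1$absorbance, d2$absorbance, tolerance = 1e-12)

  # linearity: filtering commutes with linear combination of spectra
  r <- synth_spectrum(lib$RSO, cfg, "RSO-1", 1)
  mix <- spectrum(s$wavenumbers, 0.3 * s$absorbance + 0.7 * r$absorbance)
  for (op in list(function(x) savgol_smooth(x, 11, 2),
                  function(x) first_derivative(x, 11, 3))) {
    lhs <- op(mix)$absorbance
    rhs <- 0.3 * op(s)$absorbance + 0.7 * op(r)$absorbance
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("preprocess_set smooths, differentiates, then crops in order", {
  cfg <- generator_config(noise_sd = 1e-4)
  lib <- build_endmember_library(1)
  set <- spectrum_set(list(synth_spectrum(lib$CAO, cfg, "CAO-1", 1),
                           synth_spectrum(lib$RSO, cfg, "RSO-1", 1)))

  # smoothing only, full region: equals savgol_smooth
  p0 <- preprocess_set(set, preprocess_config(derivative_order = 0,
                                              region = region_spec(4000, 650)))
  expect_identical(p0$absorbance, savgol_smooth(set, 11, 2)$absorbance)
  expect_identical(p0$meta, set$meta)

  # derivative output is restricted to the region and keeps metadata
  p1 <- preprocess_set(set, preprocess_config())
  expect_true(all(p1$wavenumbers <= 1800))
  expect_identical(p1$meta, set$meta)

  # equals filtering then cropping done by hand (crop happens last, so no
  # edge effects enter the region)
  manual <- crop_region(first_derivative(savgol_smooth(set, 11, 2), 11, 3),
                        region_spec(1800, 650))
  expect_identical(p1$absorbance, manual$absorbance)

  # sg_window = 1 bypasses smoothing for raw-spectrum analyses
  praw <- preprocess_set(set, preprocess_config(sg_window = 1,
                                                derivative_order = 0,
                                                region = region_spec(4000, 650)))
  expect_identical(praw$absorbance, set$absorbance)
})

test_that("an additive linear baseline is removed up to a constant", {
  cfg <- fp_config(noise_sd = 0)
  lib <- build_endmember_library(1)
  s <- synth_spectrum(lib$CAO, cfg, "CAO-1", 1)
  tilted <- spectrum(s$wavenumbers, s$absorbance + 2e-5 * s$wavenumbers, s$meta)
  d0 <- first_derivative(s)$absorbance
  d1 <- first_derivative(tilted)$absorbance
  expect_equal(d1 - d0, rep(2e-5, length(d0)), tolerance = 1e-12)
  expect_equal(sd(d1 - d0), 0, tolerance = 1e-15)
})
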