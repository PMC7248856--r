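test_that("endmember templates hit the mid-range ratio targets exactly", {
  lib <- build_endmember_library(1, brand_amp_cv = 0)
  cfg <- generator_config(noise_sd = 0)
  targets <- c(CAO = 1.064, RSO = 0.971, PO = 0.9805, SO = 0.948,
               CO = 0.9375, SFO = 0.9135, SBO = 0.9115)
  for (oil in names(targets)) {
    s <- synth_spectrum(lib[[oil]], cfg, "T", 1)
    expect_equal(intensity_ratio(s)$ratio, targets[[oil]], tolerance = 1e-9)
  }
})

test_that("crossover scale follows the closed form and root-finding agrees", {
  k <- crossover_scale(1.064, 0.971, 0.55)
  expect_equal(k, 0.45 * 0.064 / (0.55 * 0.029), tolerance = 1e-12)
  expect_equal(k, 1.806, tolerance = 1e-3)

  # independent oracle: root of the mixed windowed ratio on the calibrated
  # templates falls at the designed 55% v/v
  lad <- template_ladder(levels = numeric(0))
  cao <- lad[[1]]; rso <- lad[[2]]
  f <- function(v) intensity_ratio(blend_spectrum(cao, rso, 100 * v))$ratio - 1
  vstar <- uniroot(f, c(0.3, 0.8), tol = 1e-10)$root
  expect_equal(vstar, 0.55, tolerance = 1e-6)
})

test_that("noise-free synthesis equals the band sum and peaks where built", {
  cfg <- generator_config(noise_sd = 0)
  lib <- build_endmember_library(1, brand_amp_cv = 0)
  s1 <- synth_spectrum(lib$CAO, cfg, "A", 1)
  s2 <- synth_spectrum(lib$CAO, cfg, "B", 2)
  expect_identical(s1$absorbance, s2$absorbance)  # no noise, no brand effect

  # single Gaussian band of unit amplitude peaks at 1.0 at its center
  m <- lib$CAO
  m$bands <- data.frame(center = 1744, fwhm = 10, amplitude = 1,
                        unsat_scaled = FALSE)
  m$gauss_fraction <- 1
  s <- synth_spectrum(m, cfg, "A", 1)
  expect_equal(max(s$absorbance), 1.0, tolerance = 1e-12)
  expect_equal(s$wavenumbers[which.max(s$absorbance)], 1744)
})

test_that("synthesis is bitwise deterministic in (seed, brand, replicate)", {
  cfg <- generator_config(seed = 42)
  lib <- build_endmember_library(42)
  a <- synth_spectrum(lib$CAO, cfg, "CAO-1", 2)
  b <- synth_spectrum(lib$CAO, cfg, "CAO-1", 2)
  expect_identical(a$absorbance, b$absorbance)
  c <- synth_spectrum(lib$CAO, cfg, "CAO-1", 3)
  expect_false(identical(a$absorbance, c$absorbance))
  d <- synth_spectrum(lib$CAO, cfg, "CAO-2", 2)
  expect_false(identical(a$absorbance, d$absorbance))
})

test_that("blending is the exact convex combination with faithful metadata", {
  cfg <- fp_config(noise_sd = 0)
  lib <- build_endmember_library(1)
  cao <- synth_spectrum(lib$CAO, cfg, "CAO-1", 1)
  rso <- synth_spectrum(lib$RSO, cfg, "RSO-1", 1)

  expect_identical(blend_spectrum(cao, rso, 0)$absorbance, cao$absorbance)
  expect_identical(blend_spectrum(cao, rso, 100)$absorbance, rso$absorbance)

  b50 <- blend_spectrum(cao, rso, 50)
  expect_equal(b50$absorbance, (cao$absorbance + rso$absorbance) / 2)
  expect_equal(b50$meta$oil_type, "BLEND")
  expect_equal(b50$meta$blend_fraction_v, 50)
  expect_equal(b50$meta$adulterant_brand, "RSO-1")

  other <- synth_spectrum(lib$RSO, generator_config(grid_step = 4, noise_sd = 0),
                          "RSO-1", 1)
  expect_error(blend_spectrum(cao, other, 10), "grids")

  # affine property: blend lies on the segment between the endmembers
  for (v in c(10, 35, 80)) {
    bv <- blend_spectrum(cao, rso, v)
    expect_equal(bv$absorbance,
                 (1 - v / 100) * cao$absorbance + (v / 100) * rso$absorbance,
                 tolerance = 1e-15)
  }
})

test_that("the 5x3x12 design yields 180 blends and 194 total samples", {
  cfg <- fp_config(seed = 2, noise_sd = 0)
  set <- generate_design(design_table5(), cfg)
  expect_equal(sum(set$meta$oil_type == "BLEND"), 180)
  expect_equal(length(set), 194)
  expect_equal(sum(set$meta$oil_type == "CAO"), 7)
  expect_equal(sum(set$meta$oil_type == "RSO"), 7)

  tiny <- generate_design(blend_design("CAO-1", "RSO-1", 25), cfg)
  expect_equal(sum(tiny$meta$oil_type == "BLEND"), 1)
})

test_that("generated sets are bitwise reproducible under a fixed seed", {
  cfg <- fp_config(seed = 11)
  d <- blend_design(paste0("CAO-", 1:2), "RSO-1", c(5, 20), replicates = 2)
  a <- generate_design(d, cfg)
  b <- generate_design(d, cfg)
  expect_identical(a$absorbance, b$absorbance)
  expect_identical(a$meta, b$meta)
  # and global RNG state is untouched by generation
  set.seed(99); before <- .Random.seed
  invisible(generate_design(d, cfg))
  expect_identical(.Random.seed, before)
})

test_that("noise-free blend-ladder ratio decreases strictly in level", {
  rt <- ratio_table(template_ladder())
  rt <- rt[order(rt$blend_fraction_v), ]
  expect_true(all(diff(rt$ratio) < 0))
})
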