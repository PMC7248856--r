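# Synthetic spectrum generation ------------------------------------------

#' Generator configuration
#'
#' @param grid_high,grid_low,grid_step Wavenumber grid in cm-1 (stored
#'   high-to-low). The default 4000-650 at 2 cm-1 spacing gives 1676 points.
#' @param noise_sd Standard deviation of i.i.d. Gaussian measurement noise
#'   per grid point, in AU.
#' @param baseline_coeffs Polynomial baseline coefficients: the baseline is
#'   `sum(baseline_coeffs[i] * (nu/1000)^(i-1))` AU at wavenumber `nu`.
#' @param seed Integer master seed; every per-brand and per-replicate draw
#'   uses a seed derived deterministically from it.
#' @return An object of class `"generator_config"`.
#' @export
generator_config <- function(grid_high = 4000, grid_low = 650, grid_step = 2,
                             noise_sd = 2e-4, baseline_coeffs = 0, seed = 1) {
  stopifnot(grid_step > 0, grid_high > grid_low, noise_sd >= 0)
  structure(list(grid_high = grid_high, grid_low = grid_low,
                 grid_step = grid_step, noise_sd = noise_sd,
                 baseline_coeffs = as.numeric(baseline_coeffs),
                 seed = as.integer(seed)),
            class = "generator_config")
}

config_grid <- function(cfg) {
  seq(cfg$grid_high, cfg$grid_low, by = -cfg$grid_step)
}

config_baseline <- function(cfg, grid) {
  b <- numeric(length(grid))
  for (i in seq_along(cfg$baseline_coeffs))
    b <- b + cfg$baseline_coeffs[i] * (grid / 1000)^(i - 1)
  b
}

# Per-(oil, brand) band amplitude multipliers: a common log-normal intensity
# factor with CV = brand_amp_cv (ATR contact / path-length differences;
# leaves band ratios untouched) times small independent per-band log-normal
# jitter with CV = brand_amp_cv / 10 (compositional fine structure).
brand_multipliers <- function(model, cfg, brand) {
  cv <- model$brand_amp_cv
  if (cv == 0) return(rep(1, nrow(model$bands)))
  sd_common <- sqrt(log(1 + cv^2))
  sd_band <- sqrt(log(1 + (cv / 10)^2))
  with_seed(derive_seed(cfg$seed, "brand", model$oil_type, brand), {
    common <- exp(rnorm(1, -sd_common^2 / 2, sd_common))
    jitter <- exp(rnorm(nrow(model$bands), -sd_band^2 / 2, sd_band))
    common * jitter
  })
}

# Noise-free brand-level template on the config grid (multipliers applied,
# baseline included, no measurement noise).
brand_template <- function(model, cfg, brand) {
  grid <- config_grid(cfg)
  mult <- brand_multipliers(model, cfg, brand)
  eval_bands(model$bands, grid, model$gauss_fraction, mult) +
    config_baseline(cfg, grid)
}

#' Synthesize one measured spectrum of a pure oil
#'
#' The spectrum is the sum of the model's pseudo-Voigt bands (with
#' per-brand amplitude multipliers drawn once per (oil, brand) from the
#' seed), a polynomial baseline, and i.i.d. Gaussian measurement noise.
#' Replicate noise is seeded from (seed, oil, brand, replicate), so the
#' same call is bitwise reproducible.
#'
#' @param model An `endmember_model` from [build_endmember_library()].
#' @param cfg A [generator_config()].
#' @param brand Brand label, e.g. `"CAO-1"`.
#' @param replicate Positive integer replicate index.
#' @return A [spectrum()].
#' @export
synth_spectrum <- function(model, cfg, brand = paste0(model$oil_type, "-1"),
                           replicate = 1L) {
  stopifnot(inherits(model, "endmember_model"), inherits(cfg, "generator_config"))
  grid <- config_grid(cfg)
  ab <- brand_template(model, cfg, brand)
  if (cfg$noise_sd > 0) {
    ab <- ab + with_seed(
      derive_seed(cfg$seed, "rep", model$oil_type, brand, replicate),
      rnorm(length(grid), 0, cfg$noise_sd))
  }
  v <- if (model$oil_type == "RSO") 100 else 0
  spectrum(grid, ab,
           sample_meta(sprintf("%s_r%d", brand, replicate), model$oil_type,
                       blend_fraction_v = v, base_brand = brand,
                       replicate = replicate))
}

#' Mix two spectra by ideal Beer-Lambert volume blending
#'
#' `absorbance = (1 - v/100) * base + (v/100) * adulterant`, point by point
#' on a shared grid.
#'
#' @param cao Base-oil spectrum.
#' @param rso Adulterant spectrum.
#' @param v Adulterant level in % v/v, in `[0, 100]`.
#' @return A [spectrum()] whose metadata records the blend fraction and
#'   both brands.
#' @export
blend_spectrum <- function(cao, rso, v) {
  stopifnot(inherits(cao, "spectrum"), inherits(rso, "spectrum"),
            v >= 0, v <= 100)
  if (!identical(cao$wavenumbers, rso$wavenumbers))
    stop("cannot blend spectra on different wavenumber grids")
  f <- v / 100
  ab <- (1 - f) * cao$absorbance + f * rso$absorbance
  oil <- if (v == 0) cao$meta$oil_type else if (v == 100) rso$meta$oil_type else "BLEND"
  meta <- sample_meta(
    sprintf("%s_%s_v%g_r%d", cao$meta$base_brand, rso$meta$base_brand, v,
            cao$meta$replicate),
    oil, blend_fraction_v = v, base_brand = cao$meta$base_brand,
    adulterant_brand = if (v > 0) rso$meta$base_brand else "",
    replicate = cao$meta$replicate)
  spectrum(cao$wavenumbers, ab, meta)
}

#' Blend design: brands x levels x replicates
#'
#' @param cao_brands,rso_brands Brand labels whose crossings form the blend
#'   cells.
#' @param levels Adulterant levels in % v/v, each strictly inside (0, 100).
#' @param replicates Measured replicates per cell.
#' @param pure_cao_brands,pure_rso_brands Brands emitted as pure endmember
#'   samples alongside the blends (default: the blend brands).
#' @return An object of class `"blend_design"`.
#' @export
blend_design <- function(cao_brands, rso_brands, levels, replicates = 1L,
                         pure_cao_brands = cao_brands,
                         pure_rso_brands = rso_brands) {
  stopifnot(length(cao_brands) >= 1, length(rso_brands) >= 1,
            length(levels) >= 1, all(levels > 0), all(levels < 100),
            replicates >= 1)
  structure(list(cao_brands = cao_brands, rso_brands = rso_brands,
                 levels = sort(as.numeric(levels)),
                 replicates = as.integer(replicates),
                 pure_cao_brands = pure_cao_brands,
                 pure_rso_brands = pure_rso_brands),
            class = "blend_design")
}

#' The 5 x 3 x 12 calibration blend design
#'
#' Five camellia-oil brands crossed with three rapeseed-oil brands at
#' twelve levels (1-50% v/v) gives 180 blend samples; seven pure CAO and
#' seven pure RSO brands are emitted alongside, for 194 samples in total.
#'
#' @param replicates Measured replicates per blend cell (default 1).
#' @return A [blend_design()].
#' @export
design_table5 <- function(replicates = 1L) {
  blend_design(cao_brands = paste0("CAO-", 1:5),
               rso_brands = paste0("RSO-", 1:3),
               levels = blend_levels_calibration,
               replicates = replicates,
               pure_cao_brands = paste0("CAO-", 1:7),
               pure_rso_brands = paste0("RSO-", 1:7))
}

#' Generate a full blend design as a spectrum set
#'
#' Emits pure endmember spectra for the design's pure brands, then every
#' (CAO brand x RSO brand x level x replicate) blend. Blends are formed
#' from the noise-free brand templates and then receive replicate
#' measurement noise, emulating one ATR measurement of each prepared
#' mixture.
#'
#' @param design A [blend_design()].
#' @param cfg A [generator_config()].
#' @param library Endmember library; defaults to
#'   `build_endmember_library(cfg$seed)`.
#' @return A [spectrum_set()].
#' @export
generate_design <- function(design, cfg = generator_config(),
                            library = build_endmember_library(cfg$seed)) {
  stopifnot(inherits(design, "blend_design"), inherits(cfg, "generator_config"))
  cao <- library[["CAO"]]; rso <- library[["RSO"]]
  out <- list()
  for (b in design$pure_cao_brands)
    for (r in seq_len(design$replicates))
      out[[length(out) + 1]] <- synth_spectrum(cao, cfg, b, r)
  for (b in design$pure_rso_brands)
    for (r in seq_len(design$replicates))
      out[[length(out) + 1]] <- synth_spectrum(rso, cfg, b, r)
  grid <- config_grid(cfg)
  for (cb in design$cao_brands) {
    cao_t <- brand_template(cao, cfg, cb)
    for (rb in design$rso_brands) {
      rso_t <- brand_template(rso, cfg, rb)
      for (v in design$levels) {
        mix <- (1 - v / 100) * cao_t + (v / 100) * rso_t
        for (r in seq_len(design$replicates)) {
          ab <- mix
          if (cfg$noise_sd > 0) {
            ab <- ab + with_seed(
              derive_seed(cfg$seed, "blend", cb, rb, v, r),
              rnorm(length(grid), 0, cfg$noise_sd))
          }
          meta <- sample_meta(sprintf("%s_%s_v%g_r%d", cb, rb, v, r), "BLEND",
                              blend_fraction_v = v, base_brand = cb,
                              adulterant_brand = rb, replicate = r)
          out[[length(out) + 1]] <- spectrum(grid, ab, meta)
        }
      }
    }
  }
  spectrum_set(out)
}

#' Generate a grouped classification set of pure CAO and low-level blends
#'
#' One group per entry of `levels` (0 = pure CAO), each realized as
#' `cao_brands x replicates` measured spectra; blends use a single RSO
#' brand. With the defaults this yields the 5-groups-by-15-replicates
#' layout used for LDA screening (75 spectra).
#'
#' @param levels Blend levels in % v/v (0 allowed, meaning pure CAO).
#' @param cfg A [generator_config()].
#' @param cao_brands CAO brand labels (default CAO-1..CAO-5).
#' @param rso_brand Single adulterant brand (default RSO-1).
#' @param replicates Replicate measurements per brand (default 3).
#' @param library Endmember library; defaults to
#'   `build_endmember_library(cfg$seed)`.
#' @return A [spectrum_set()]; group membership is recoverable from the
#'   `blend_fraction_v` metadata column (see [blend_group_labels()]).
#' @export
generate_classification_set <- function(levels = c(0, 1, 3, 5, 10),
                                        cfg = generator_config(),
                                        cao_brands = paste0("CAO-", 1:5),
                                        rso_brand = "RSO-1",
                                        replicates = 3L,
                                        library = build_endmember_library(cfg$seed)) {
  stopifnot(all(levels >= 0), all(levels < 100))
  cao <- library[["CAO"]]; rso <- library[["RSO"]]
  grid <- config_grid(cfg)
  rso_t <- brand_template(rso, cfg, rso_brand)
  out <- list()
  for (v in levels) {
    for (cb in cao_brands) {
      cao_t <- brand_template(cao, cfg, cb)
      mix <- (1 - v / 100) * cao_t + (v / 100) * rso_t
      for (r in seq_len(replicates)) {
        ab <- mix
        if (cfg$noise_sd > 0) {
          ab <- ab + with_seed(
            derive_seed(cfg$seed, "cls", cb, rso_brand, v, r),
            rnorm(length(grid), 0, cfg$noise_sd))
        }
        meta <- sample_meta(sprintf("%s_%s_v%g_r%d", cb, rso_brand, v, r),
                            if (v == 0) "CAO" else "BLEND",
                            blend_fraction_v = v, base_brand = cb,
                            adulterant_brand = if (v > 0) rso_brand else "",
                            replicate = r)
        out[[length(out) + 1]] <- spectrum(grid, ab, meta)
      }
    }
  }
  spectrum_set(out)
}

#' Group labels ("CAO", "RSO 1%", ...) from blend metadata
#'
#' @param meta Metadata `data.frame` of a [spectrum_set()].
#' @return Character vector of group labels.
#' @export
blend_group_labels <- function(meta) {
  ifelse(meta$blend_fraction_v == 0, meta$oil_type,
         sprintf("RSO %g%%", meta$blend_fraction_v))
}

#' Generate the noise-free CAO/RSO template blend ladder
#'
#' Blends the calibrated noise-free CAO and RSO endmember templates (no
#' brand perturbation, no noise, no baseline) at the given levels plus the
#' two pure endpoints.
#'
#' @param levels Blend levels in % v/v (default: the full 1-90% ladder).
#' @param cfg A [generator_config()] (grid definition; noise ignored).
#' @param library Endmember library.
#' @return A [spectrum_set()] with levels 0, `levels`, 100.
#' @export
template_ladder <- function(levels = blend_levels_full,
                            cfg = generator_config(noise_sd = 0),
                            library = build_endmember_library(cfg$seed)) {
  grid <- config_grid(cfg)
  cao_t <- eval_bands(library$CAO$bands, grid, library$CAO$gauss_fraction)
  rso_t <- eval_bands(library$RSO$bands, grid, library$RSO$gauss_fraction)
  cao_s <- spectrum(grid, cao_t, sample_meta("CAO_template", "CAO",
                                             base_brand = "CAO-T"))
  rso_s <- spectrum(grid, rso_t, sample_meta("RSO_template", "RSO",
                                             blend_fraction_v = 100,
                                             base_brand = "RSO-T"))
  out <- lapply(sort(unique(c(0, levels, 100))),
                function(v) blend_spectrum(cao_s, rso_s, v))
  spectrum_set(out)
}
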