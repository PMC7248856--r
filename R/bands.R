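# Endmember band models for the seven edible oils ------------------------
#
# Each oil is a sum of pseudo-Voigt bands at the canonical triacylglycerol
# absorption positions (=C-H and C-H stretches, ester C=O, CH2/CH3 bending,
# the two ester C-O stretches at 1119/1096 cm-1, and the cis CH=CH rock at
# 722 cm-1). The two C-O band amplitudes are calibrated per oil so the
# windowed peak-height ratio I1119/I1096 of the noise-free template hits the
# midpoint of that oil's observed pure-oil range, and the absolute C-O scale
# of RSO relative to CAO is set so the blend-series ratio crosses the 1.000
# purity threshold at 55% v/v rapeseed oil.

#' The seven marker wavenumbers used for LDA classification
#'
#' C=O stretch (1744), CH2/CH3 bending (1464, 1377), C-O stretches
#' (1155, 1119, 1096) and the cis CH=CH rock (721 cm-1).
#' @export
lda_marker_wavenumbers <- c(1744, 1464, 1377, 1155, 1119, 1096, 721)

#' Blend levels (% v/v rapeseed oil) of the full admixture ladder
#' @export
blend_levels_full <- c(1, 3, 5, 10, 15, 20, 25, 30, 35, 40, 45, 50, 60, 70, 80, 90)

#' Blend levels used for calibration models (0-50% v/v)
#' @export
blend_levels_calibration <- c(1, 3, 5, 10, 15, 20, 25, 30, 35, 40, 45, 50)

# Noise-free template I1119/I1096 targets: midpoints of the observed
# pure-oil ratio ranges.
RATIO_TARGETS <- c(CAO = 1.064, RSO = 0.971, PO = 0.9805, SO = 0.948,
                   CO = 0.9375, SFO = 0.9135, SBO = 0.9115)

# Total unsaturated fatty-acid content (% of fatty acids, GC-FID profiles)
UNSAT_TOTALS <- c(CAO = 87.10, SBO = 84.67, CO = 84.70, RSO = 92.91,
                  SFO = 88.07, PO = 78.32, SO = 84.48)

# Major acyl fractions (% of fatty acids) driving per-oil band intensities:
# oleic (C18:1), linoleic (C18:2) and total polyunsaturated (C18:2 + C18:3)
OLEIC <- c(CAO = 76.46, SBO = 23.17, CO = 31.61, RSO = 64.05,
           SFO = 22.94, PO = 40.87, SO = 38.79)
LINOLEIC <- c(CAO = 10.25, SBO = 54.09, CO = 51.71, RSO = 21.16,
              SFO = 64.68, PO = 36.14, SO = 45.01)
LINOLENIC <- c(CAO = 0.15, SBO = 7.37, CO = 1.09, RSO = 6.29,
               SFO = 0.17, PO = 0.18, SO = 0.44)
PUFA <- c(CAO = 10.40, SBO = 61.46, CO = 52.80, RSO = 27.45,
          SFO = 64.85, PO = 36.32, SO = 45.45)

# Fixed band table: centers (cm-1), widths, base amplitudes (AU), and
# whether the band tracks total unsaturation. The 1119/1096 amplitudes
# listed here are starting values for the calibration solver.
BASE_BANDS <- data.frame(
  center = c(3006, 2923, 2853, 1744, 1464, 1377, 1240, 1160, 1119, 1096, 722),
  fwhm = c(12, 22, 18, 16, 14, 10, 14, 18, 12, 12, 14),
  amplitude = c(0.035, 0.28, 0.20, 0.32, 0.048, 0.036, 0.026, 0.080,
                0.105, 0.100, 0.065),
  unsat_scaled = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                   FALSE, FALSE, TRUE)
)

# Reference peak height of the 1096 cm-1 band on the CAO template (AU).
CO_BAND_HEIGHT_REF <- 0.10

# Continuous blend level (volume fraction) at which the CAO/RSO ratio is
# calibrated to cross the 1.000 purity threshold.
CROSSOVER_V <- 0.55

#' Relative C-O band scale of the adulterant required for a given crossover
#'
#' For endmember C-O peak heights with ratios `r_base` (>1) and `r_adult`
#' (<1), linear volume mixing crosses ratio 1 at volume fraction `v_star`
#' when the adulterant's 1096 cm-1 height is `k` times the base oil's:
#' `k = (1 - v_star) * (r_base - 1) / (v_star * (1 - r_adult))`.
#'
#' @param r_base,r_adult Template peak-height ratios of base oil and
#'   adulterant.
#' @param v_star Target crossover volume fraction in (0, 1).
#' @return The scale factor `k`.
#' @export
crossover_scale <- function(r_base, r_adult, v_star = CROSSOVER_V) {
  stopifnot(v_star > 0, v_star < 1, r_base > 1, r_adult < 1)
  (1 - v_star) * (r_base - 1) / (v_star * (1 - r_adult))
}

#' Pseudo-Voigt profile with unit peak height
#' @noRd
pseudo_voigt <- function(nu, center, fwhm, gauss_fraction) {
  u <- (nu - center) / fwhm
  gauss_fraction * exp(-log(2) * 4 * u^2) +
    (1 - gauss_fraction) / (1 + 4 * u^2)
}

#' Evaluate a band-model template on a grid (noise-free, no baseline)
#' @noRd
eval_bands <- function(bands, grid, gauss_fraction = 0.7, multipliers = 1) {
  multipliers <- rep_len(multipliers, nrow(bands))
  acc <- numeric(length(grid))
  for (i in seq_len(nrow(bands))) {
    acc <- acc + bands$amplitude[i] * multipliers[i] *
      pseudo_voigt(grid, bands$center[i], bands$fwhm[i], gauss_fraction)
  }
  acc
}

# Solve the 1119/1096 amplitudes of one oil so the windowed peak heights of
# the noise-free template equal (ratio * h96_target, h96_target). The two
# heights are affine in the two amplitudes once the argmax grid points are
# fixed, so we alternate a 2x2 linear solve with argmax relocation.
calibrate_co_bands <- function(bands, grid, ratio_target, h96_target,
                               gauss_fraction = 0.7, half_window = 4,
                               tol = 1e-13, max_iter = 60) {
  i19 <- which(bands$center == 1119)
  i96 <- which(bands$center == 1096)
  others <- bands[-c(i19, i96), , drop = FALSE]
  bg <- eval_bands(others, grid, gauss_fraction)
  w19 <- which(abs(grid - 1119) <= half_window)
  w96 <- which(abs(grid - 1096) <= half_window)
  phi19 <- pseudo_voigt(grid, 1119, bands$fwhm[i19], gauss_fraction)
  phi96 <- pseudo_voigt(grid, 1096, bands$fwhm[i96], gauss_fraction)
  a19 <- bands$amplitude[i19]
  a96 <- bands$amplitude[i96]
  targets <- c(ratio_target * h96_target, h96_target)
  for (iter in seq_len(max_iter)) {
    spec <- bg + a19 * phi19 + a96 * phi96
    p19 <- w19[which.max(spec[w19])]
    p96 <- w96[which.max(spec[w96])]
    A <- rbind(c(phi19[p19], phi96[p19]),
               c(phi19[p96], phi96[p96]))
    sol <- solve(A, targets - c(bg[p19], bg[p96]))
    delta <- max(abs(sol - c(a19, a96)))
    a19 <- sol[1]; a96 <- sol[2]
    if (delta < tol) break
  }
  if (a19 <= 0 || a96 <= 0)
    stop("C-O band calibration produced non-positive amplitude")
  bands$amplitude[i19] <- a19
  bands$amplitude[i96] <- a96
  bands
}

#' Build calibrated endmember band models for the seven oils
#'
#' Band amplitudes are calibrated so that (a) each oil's noise-free
#' template has a windowed I1119/I1096 peak-height ratio equal to the
#' midpoint of its observed pure-oil range, (b) the unsaturation-sensitive
#' bands (3006 and 722 cm-1) scale with the oil's total unsaturated
#' fatty-acid content, and (c) RSO's absolute C-O band scale relative to
#' CAO places the blend-ratio crossover at 55% v/v, so the tabulated ladder
#' first drops below 1.000 at the 60% level.
#'
#' @param seed Integer stored in the models and used (together with brand
#'   labels) to derive per-brand amplitude perturbations at synthesis time.
#' @param brand_amp_cv Relative standard deviation of the per-brand
#'   amplitude perturbation (dimensionless).
#' @param grid_step Grid step (cm-1) used when calibrating the windowed
#'   peak heights.
#' @param gauss_fraction Pseudo-Voigt Gaussian fraction shared by all bands.
#' @return Named list of `endmember_model` objects, one per oil type
#'   (CAO, RSO, SBO, CO, SFO, PO, SO).
#' @export
build_endmember_library <- function(seed = 1, brand_amp_cv = 0.01,
                                    grid_step = 2, gauss_fraction = 0.7) {
  grid <- seq(4000, 650, by = -grid_step)
  k <- crossover_scale(RATIO_TARGETS[["CAO"]], RATIO_TARGETS[["RSO"]])
  lib <- lapply(names(RATIO_TARGETS), function(oil) {
    bands <- BASE_BANDS
    scale_u <- UNSAT_TOTALS[[oil]] / UNSAT_TOTALS[["CAO"]]
    bands$amplitude[bands$unsat_scaled] <-
      bands$amplitude[bands$unsat_scaled] * scale_u
    # CH2/CH3 bending intensities shift with the acyl profile; the cis
    # CH=CH rock at 722 cm-1 additionally tracks linolenate (3 cis bonds)
    d_ole <- (OLEIC[[oil]] - OLEIC[["CAO"]]) / 100
    d_lin <- (LINOLEIC[[oil]] - LINOLEIC[["CAO"]]) / 100
    d_len <- (LINOLENIC[[oil]] - LINOLENIC[["CAO"]]) / 100
    scl <- c("1377" = 1 + 1.0 * d_lin, "1464" = 1 - 0.8 * d_lin,
             "1240" = 1 + 0.5 * d_ole, "1160" = 1 - 0.4 * d_ole,
             "722" = 1 + 2.5 * d_len)
    for (ctr in names(scl)) {
      i <- bands$center == as.numeric(ctr)
      bands$amplitude[i] <- bands$amplitude[i] * scl[[ctr]]
    }
    # absolute ester C-O scale: pinned by the crossover calibration for
    # RSO, tracking polyunsaturation for the remaining oils
    h96 <- if (oil == "RSO") k * CO_BAND_HEIGHT_REF
      else CO_BAND_HEIGHT_REF * (1 + (PUFA[[oil]] - PUFA[["CAO"]]) / 100)
    bands <- calibrate_co_bands(bands, grid, RATIO_TARGETS[[oil]], h96,
                                gauss_fraction)
    structure(list(oil_type = oil, bands = bands,
                   gauss_fraction = gauss_fraction,
                   brand_amp_cv = brand_amp_cv, seed = seed),
              class = "endmember_model")
  })
  names(lib) <- names(RATIO_TARGETS)
  lib
}

#' @export
print.endmember_model <- function(x, ...) {
  cat(sprintf("<endmember_model> %s: %d bands, brand_amp_cv = %g\n",
              x$oil_type, nrow(x$bands), x$brand_amp_cv))
  invisible(x)
}
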