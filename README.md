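# camspec

Chemometric authentication of camellia oil (CAO) from ATR-FTIR spectra:
screening for and quantifying adulteration with rapeseed oil (RSO).

Camellia oil is a high-oleic premium oil; rapeseed oil is its most likely
adulterant because the two acyl profiles are close. Mid-infrared spectra
of edible oils are dominated by triacylglycerol bands whose relative
intensities track fatty-acid composition, which makes a fast spectroscopic
screen possible. `camspec` is aimed at analysts building or studying such
screens: it implements the full workflow as composable R functions with
classed model objects, and ships a calibrated synthetic spectrum generator
so the entire pipeline runs, and is tested, without instrument data.

## What it computes

- **Purity ratio** — the ester C–O band-height ratio
  *I*₁₁₁₉/*I*₁₀₉₆ (windowed peak maxima, half-window 4 cm⁻¹). Pure CAO
  shows *I*₁₁₁₉/*I*₁₀₉₆ > 1.000; other oils and CAO/RSO blends beyond the
  mid-50s % v/v fall below it. For the calibrated endmembers the blend
  ratio crosses 1.000 at v\* = 55% v/v, so the tabulated ladder
  (…, 50, 60, … %) first drops below 1.000 at 60%.
- **Savitzky–Golay preprocessing** — smoothing (window 11, order 2) and
  first derivative (order 3), then cropping to the fingerprint region
  1800–650 cm⁻¹.
- **PCA** (`pca_fit`) — mean-centering + SVD, per-region explained
  variance, and loading-based selection of influential wavenumbers, which
  recovers the seven markers 1744, 1464, 1377, 1155, 1119, 1096, 721 cm⁻¹.
- **LDA** (`lda_fit`) — nearest class mean in the Mahalanobis metric of
  the pooled within-class covariance, equal priors; resubstitution and
  leave-one-out confusion matrices (`loo_cross_validate`).
- **PLSR** (`plsr_fit`) — single-response NIPALS with regression vector
  *B* = *W*(*P*ᵀ*W*)⁻¹*q*; figures of merit slope, offset, R², RMSEC and
  RMSECV (`figures_of_merit`, `run_calibration_suite`).
- **`run_full()`** — a seeded end-to-end run writing CSV tables and a
  byte-reproducible JSON summary.

## Worked example

```r
library(camspec)

cfg <- generator_config(seed = 1)              # 4000-650 cm-1, 2 cm-1 grid
lib <- build_endmember_library(1)              # calibrated 7-oil band models

## the LDA screen: pure CAO and 1, 3, 5, 10% v/v RSO, 15 replicates each
set <- generate_classification_set(levels = c(0, 1, 3, 5, 10),
                                   cfg = cfg, library = lib)
set
#> <spectrum_set> 75 spectra, 1676 points, 4000-650 cm-1
#>   oil types: BLEND(60) CAO(15)

## purity ratios of the pure camellia spectra (smoothed)
round(range(ratio_table(savgol_smooth(set[set$meta$blend_fraction_v == 0]))$ratio), 4)
#> [1] 1.0693 1.0773

## leave-one-out LDA on the seven marker wavenumbers
feats <- extract_features(savgol_smooth(set), lda_marker_wavenumbers)
loo_cross_validate(feats)
#> LOO cross-validated: 100.00% correct | resubstitution: 100.00%
#>          predicted
#> truth     CAO RSO 1% RSO 10% RSO 3% RSO 5%
#>   CAO      15      0       0      0      0
#>   RSO 1%    0     15       0      0      0
#>   RSO 10%   0      0      15      0      0
#>   RSO 3%    0      0       0     15      0
#>   RSO 5%    0      0       0      0     15

## the 15-model PLSR calibration campaign (5 CAO x 3 RSO brands, 0-50% v/v)
design <- generate_design(design_table5(), cfg, lib)
suite <- run_calibration_suite(design, factors = 4)
head(suite[, c("rso_brand", "cao_brand", "slope", "rmsec", "r2", "rmsecv")], 3)
#>   rso_brand cao_brand slope   rmsec r2 rmsecv
#> 1     RSO-1     CAO-1     1 0.00169  1  0.192
#> 2     RSO-1     CAO-2     1 0.00251  1  0.159
#> 3     RSO-1     CAO-3     1 0.00459  1  0.149
```

All 21 pure-camellia ratios fall inside the observed pure-CAO window
(1.045–1.083) and above the 1.000 threshold; every group of the LDA
screen — down to 1% v/v RSO — is classified perfectly under
cross-validation; and each of the 15 calibration models predicts the blend
fraction with slope ≈ 1 and cross-validated error of ≈ 0.2% v/v under the
default noise model.

## Package layout

- `R/` — spectra containers and IO, synthetic generator, preprocessing,
  ratio screen, PCA, LDA, PLSR, pipeline.
- `tests/testthat/` — unit, property and study-level tests (all fixtures
  generated in code).
- `vignettes/camellia-oil-authentication.Rmd` — the model, its
  assumptions, calibration of the generator, and design decisions.
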