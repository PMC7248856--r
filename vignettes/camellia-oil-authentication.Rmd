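---
title: "Authenticating camellia oil from ATR-FTIR spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Authenticating camellia oil from ATR-FTIR spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(camspec)
```

## The problem

Camellia oil (CAO) commands a premium over commodity oils and is routinely
adulterated with rapeseed oil (RSO), whose fatty-acid profile is close
enough to camellia's that low blend levels are invisible to the naked eye.
Mid-infrared ATR-FTIR spectroscopy offers a fast, non-destructive screen:
triacylglycerol absorption bands dominate the spectrum, and their relative
intensities shift with the acyl composition of the oil. `camspec`
implements a complete screening-and-quantification workflow on top of
absorbance spectra:

1. a **band-ratio purity statistic** — the ratio of the ester C–O
   stretching band heights at 1119 and 1096 cm⁻¹, with ratio > 1.000 as
   the pure-camellia signature;
2. **Savitzky–Golay preprocessing** — smoothing and first derivative;
3. **PCA** for spectral-region comparison and loading-based wavenumber
   selection;
4. **LDA** on seven marker wavenumbers for classifying pure CAO against
   1–10% v/v RSO blends, with leave-one-out (LOO) cross-validation;
5. **NIPALS PLSR** for quantifying the blend fraction, with slope,
   offset, R², RMSEC and RMSECV as figures of merit.

Because no public spectral set accompanies this problem, the package ships
a **calibrated synthetic generator** that emulates the statistical
structure the analysis assumes. Every model stage is exercised — and every
claim below is computed — on generated data.

## The spectral model

A pure-oil spectrum is a sum of pseudo-Voigt bands at the canonical
triacylglycerol positions (3006, 2923, 2853, 1744, 1464, 1377, 1240, 1160,
1119, 1096, 722 cm⁻¹), plus an optional polynomial baseline and i.i.d.
Gaussian measurement noise:

$$A(\nu) \;=\; \sum_b a_b\, m_b \,\phi\!\left(\frac{\nu - c_b}{w_b}\right)
 \;+\; p(\nu) \;+\; \varepsilon(\nu), \qquad
 \varepsilon(\nu) \sim N(0, \sigma^2)$$

where $\phi$ mixes a Gaussian and a Lorentzian of common FWHM ($\eta =
0.7$ Gaussian fraction by default) and $m_b$ are per-brand amplitude
multipliers. Blends obey ideal Beer–Lambert volume mixing: the absorbance
of a $v\%$ v/v blend is the convex combination $(1 - v/100)\,A_\mathrm{CAO}
+ (v/100)\,A_\mathrm{RSO}$, pointwise on the grid. Density corrections to
v/v mixing are omitted; they are below the noise floor at these levels.

### Calibration of the endmembers

Three observable constraints pin the generator:

- **Per-oil ratio targets.** The two C–O band amplitudes of each oil are
  solved (a 2×2 linear solve alternated with peak relocation, converged to
  machine precision) so the *windowed peak-height* ratio
  $I_{1119}/I_{1096}$ of the noise-free template equals the midpoint of
  the range observed for that species: CAO 1.064, RSO 0.971, PO 0.9805,
  SO 0.948, CO 0.9375, SFO 0.9135, SBO 0.9115. The same windowed-maximum
  rule used by the analysis is used by the calibration, so the targets are
  met under the measurement, not just at band centers.
- **The 55% crossover.** For a CAO/RSO blend ladder the ratio must fall
  through 1.000 between the 50% and 60% levels. With template ratios
  $r_c > 1 > r_r$, linear mixing crosses 1 at volume fraction $v^\*$ when
  RSO's 1096 cm⁻¹ height is $k$ times CAO's:
  $$k = \frac{(1 - v^\*)(r_c - 1)}{v^\*(1 - r_r)} \approx 1.81
  \quad (v^\* = 0.55).$$
  `crossover_scale()` exposes the closed form; root-finding on the mixed
  windowed ratio of the calibrated templates recovers $v^\* = 0.55$ to
  6 decimals, and the tabulated ladder (…, 50, 60, …) first dips below
  1.000 at 60%.
- **Composition coupling.** Band intensities track the GC fatty-acid
  profile of each species: the unsaturation-sensitive bands (3006,
  722 cm⁻¹) scale with total unsaturated content; the CH₃/CH₂ bending
  bands (1377/1464) shift with linoleate and (1240/1160) with oleate; the
  cis CH=CH rock (722 cm⁻¹) additionally tracks linolenate; and the
  absolute C–O scale follows polyunsaturate content (except RSO, pinned
  by the crossover). Coefficients are fixed so that between-species band
  differences reach the 10–20% scale seen between real edible oils —
  this is what makes the seven oils occupy distinct positions in
  fingerprint-region PCA score space while soybean and sunflower (nearly
  identical acyl profiles) remain the closest pair.

### Brand variability and noise

Each (oil, brand) pair draws a **common log-normal intensity factor**
with CV `brand_amp_cv` (default 0.01) applied to all bands — emulating
ATR contact, effective path length, and overall concentration differences
— plus small **independent per-band jitter** (CV `brand_amp_cv`/10) for
compositional fine structure. The split matters: a common factor cancels
exactly in any band ratio, so the pure-CAO ratio spread across brands
stays inside the observed 1.045–1.083 window, while fully independent
per-band perturbations at CV 0.01 would spread the ratio roughly ±1.4%
and spill outside it. Replicate measurements add white noise of
`noise_sd` = 2×10⁻⁴ AU per point. All draws are seeded deterministically
from `(seed, oil, brand, replicate)`, so any generated set is bitwise
reproducible and generation never perturbs R's global RNG stream.

The generator does **not** emulate water-vapor/CO₂ interference, ATR
penetration-depth dispersion, band-center shifts between brands,
temperature effects, or ternary blends. Passing tests therefore
demonstrate the chemometric machinery under the stated noise model, not
robustness to every instrumental artifact of real spectra.

## Preprocessing choices

`savgol_smooth()` (window 11, order 2) and `first_derivative()` (window
11, order 3) are conventional settings for 2 cm⁻¹-spaced FTIR exports;
both are exposed in `preprocess_config()`. The chain is fixed as smooth →
derivative → crop so that cropping never exposes filter edge effects
inside the modelling region. A window of 1 in `preprocess_set()` is an
explicit bypass for raw-spectrum analyses; `savgol_smooth()` itself
rejects windows below 3.

Which stages consume which form:

- the **purity ratio** uses smoothed, *non-derivative* spectra — peak
  height is meaningless after differentiation;
- **PCA exploration and wavenumber selection** also use smoothed
  non-derivative spectra. Two reasons. Loading maxima of derivative
  spectra sit on band *flanks*, while wavenumber selection must report
  band centers. And differentiation whitens the broad-band mixing signal
  relative to white noise: on the admixture set the first three PCs carry
  ≈ 96.5% of derivative-spectrum variance but ≥ 98% of smoothed-spectrum
  variance, the latter matching what full-resolution studies report;
- **LDA features** are smoothed absorbances at the seven markers
  (1744, 1464, 1377, 1155, 1119, 1096, 721 cm⁻¹), following the
  precedent of classifying on raw band absorbances;
- **PLSR** consumes first-derivative spectra cropped to 1800–650 cm⁻¹,
  where baseline offsets between samples would otherwise enter the
  calibration.

## Model details and numerical choices

**PCA** (`pca_fit`) is mean-centering plus SVD — no variance scaling,
since all variables share units (AU). Explained variance is
$100\,\sigma_i^2/\sum_j \sigma_j^2$ over all $\min(n-1, p)$ components.
Loadings carry a fixed sign convention (largest-magnitude element
positive) so score plots reproduce. Wavenumber selection combines the
first three components' absolute loadings weighted by explained variance
and greedily takes local maxima with a 10 cm⁻¹ minimum separation, ties
toward the higher wavenumber; grid endpoints count as maxima against
their single neighbor.

**LDA** (`lda_fit`) uses the pooled within-class covariance
$\sum_g (n_g - 1) S_g / (n - G)$, equal priors, and nearest class mean in
the Mahalanobis metric; exact distance ties go to the lexicographically
first label. A ridge $\lambda I$ with $\lambda = 10^{-8}\,\mathrm{tr}(S)/p$
is applied only when the condition number exceeds $10^{10}$. The
5-groups × 15-replicates screen is realized as 5 CAO brands × 3
replicates per group; the replicate spectra stay separate rows
(measurements are never averaged before modelling).

**PLSR** (`plsr_fit`) is single-response NIPALS: closed-form weights per
factor, deflation of both blocks, regression vector
$B = W(P^TW)^{-1}q$. When the residual X–y covariance vanishes (exact
low-rank data) extraction stops early and the extracted factors are kept.
RMSEC uses denominator $n$ (plain root-mean-square, matching the RMSECV
definition); slope/offset come from regressing *predicted on actual*;
R² is the squared Pearson correlation. Predictions are never clipped to
[0, 100] — clipping would bias RMSECV. Each calibration model covers one
(CAO brand, RSO brand) pair at 13 levels (0–50% v/v) with 4 factors;
higher levels are excluded because the ratio screen already flags them.

## Problem sizes and determinism

The bundled study conditions are deliberately modest: 75 spectra for the
LDA screen, 194 for the calibration campaign (180 blends + 14 pure), 105
for the admixture PCA, 1676 grid points for a full 4000–650 cm⁻¹ spectrum
at 2 cm⁻¹ spacing. A complete `run_full()` — generation through the
15-model PLSR table — takes a few seconds on one core, and identical
configurations produce byte-identical JSON summaries.

## Known limitations

- The absolute absorbance scale is conventional (C–O reference height
  0.10 AU); only ratios and relative geometry are calibrated to
  observations.
- The $k \approx 1.81$ RSO/CAO C–O scale is inferred from the crossover
  interval, not measured; it is a calibration assumption of the
  generator.
- The composition-to-amplitude couplings are linearized and their
  coefficients are design choices at the realism scale, not fitted
  constants.
- LDA assumes a shared within-class covariance; with strongly
  heteroscedastic real data a quadratic rule could outperform it.
- Cross-validation is leave-one-out throughout; no external test set is
  modelled.
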