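---
title: "Estimating plant water content from canopy reflectance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating plant water content from canopy reflectance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Plant water content (PWC) of winter wheat is defined on a dry-weight
basis,

$$\mathrm{PWC}\,(\%) = \frac{FW - DW}{DW} \times 100,$$

where $FW$ and $DW$ are the fresh and dry weights of a plot sample.
Because the denominator is the dry weight, healthy wheat routinely has
PWC well above 100%; across a season under differential irrigation the
plot-level values range from roughly 50% (senescing, droughted) to 400%
(young, well-watered). The goal of this package's workflow is to
estimate PWC nondestructively from proximal canopy reflectance spectra
(350–2,500 nm) using partial least squares regression (PLSR), and to
find the small set of wavelengths — *sensitive bands* — that carry the
signal.

The workflow mirrors a two-season irrigation trial: season one
(2 cultivars × 5 irrigation upper limits W1–W5 × 3 replicate plots ×
5 sampling dates = 150 records) calibrates every model; season two
(2 cultivars × 5 irrigation frequencies I1–I5 × 3 plots × 4 dates = 120
records) is used exclusively for external validation. No parameter of
any kind — smoothing, MSC reference, centering, latent-variable count,
band selection — is derived from the validation season.

## The synthetic scene

No field data accompany the study design, so `generate_dataset()`
produces datasets with the statistical structure the analysis assumes.
The generator is a first-class, tested component, not a fixture. Its
layers, with defaults in `scene_params()`:

**PWC trajectories** (`simulate_pwc()`). Mean PWC declines linearly
from a treatment-dependent start (400% for the wettest treatment,
−18% per treatment rank) to a treatment-dependent end (150%, −26% per
rank), with a ±4% cultivar offset and Gaussian plot noise (sd 6%).
A linear decline is the simplest shape consistent with a monotone
seasonal dry-down; treatment separations are chosen large relative to
the plot noise so that the ordering of treatment means is a structural
property, not a lucky draw.

**Reflectance** (`simulate_reflectance()`, `canopy_reflectance()`). A
smooth green-canopy baseline (dark visible, green bump at 550 nm,
logistic red edge near 720 nm, NIR plateau ≈ 0.46, declining SWIR)
minus planted absorption, linearly mixed with a featureless bright soil
endmember, then per-sample scatter and white noise. The planted
absorption has four channels, each scaled by a saturating Beer–Lambert
style response $1 - e^{-\mathrm{PWC}/p_0}$:

* *Water features* at 970, 1,200, 1,450, 1,750, 1,950 and 2,250 nm,
  each the sum of a narrow Gaussian core (σ = 6–8 nm) and a broad
  shallow base (σ = 55–80 nm). The narrow cores make the planted
  positions sharply localized, so recovery by a selection method can be
  judged against a ±10 nm window; the broad bases spread water
  sensitivity between the centers, as in real canopies. The 1,750 nm
  feature is kept shallower than the dominant bands (gain 0.15 vs
  0.17–0.22), reflecting its secondary role among the classical water
  absorption bands.
* *A liquid-water continuum* rising as the square root of wavelength
  beyond 800 nm (depth 0.07 at 2,500 nm), which keeps the
  reflectance–PWC correlation negative throughout the 900–2,450 nm
  window even between feature centers.
* *Chlorophyll valleys* at 500 and 680 nm (σ = 7 nm), coupling the
  visible region indirectly to water status through greenness.
* *Per-feature saturation scales* (`pwc_reference`, 100–260%): strong
  absorption bands saturate at lower water content than weak ones.
  This is the decisive realism ingredient: with a single shared scale
  the scene is rank-one, cross-validation honestly selects one latent
  variable, and band selection degenerates. With per-feature scales the
  PWC information is genuinely multivariate and LOOCV selects multi-LV
  models, as with real spectra.

Three stochastic layers decorrelate the bands from a single factor:
log-normal per-feature depth jitter (sd 0.16; each feature is then
*marginally* informative, which is what lets stepwise regression keep
one band per feature), smooth "canopy architecture" deformations (six
random broad Gaussians per sample, amplitude sd 0.012 — the
PWC-unrelated interference that multi-LV models must span), and
per-sample multiplicative/additive scatter (sd 0.015/0.004 — exactly
what MSC is designed to remove) plus white instrument noise
(sd 0.003).

**Soil.** The soil fraction decreases linearly with irrigation level
over [0.08, 0.18] (sd 0.02): droughted canopies are sparser, so soil
contributes more under stress. The soil endmember is brighter than the
water-absorbing canopy across the SWIR but close to the canopy plateau
in the NIR; a darker NIR soil would flip the sign of the
reflectance–PWC correlation around 900–950 nm, contradicting the
negative sign structure the analysis assumes.

**The informative-band registry** defaults to the unmasked water-band
centers {970, 1,200, 1,450, 1,750, 2,250}. The chlorophyll valleys are
planted but deliberately not claimed as registry entries: they are
indirect proxies whose correlation is systematically weaker than the
direct water bands. 1,950 nm is excluded because the water-vapor mask
removes it. In the planted-signal checks, "background" bands are those
farther than 25 nm from every planted center — a band sitting on a
planted core or flank carries the planted signal by construction and
cannot honestly be counted as uninformative.

**What the generator does not emulate.** Radiative transfer
(PROSAIL-class leaf/canopy physics), BRDF geometry, weather-driven
soil-moisture dynamics, sensor-specific band response, and any
between-plot spatial correlation. Consequently, tests passing on this
scene show that the *algorithms* behave as specified on data with the
assumed structure — not that the same accuracy would be reached on
field spectra.

## Preprocessing

The order is fixed: Savitzky–Golay smoothing on the full grid → trim
and mask → transform.

* **Savitzky–Golay** (`sg_smooth()`): window 5 bands, degree 2. Edges
  use shrinking one-sided least-squares fits of the same degree, so
  output length equals input length and constants/quadratics are
  reproduced exactly.
* **Mask** (`spectral_mask()`): retain [400, 2,450] nm; remove the
  closed water-vapor intervals [1,350, 1,400] and [1,800, 1,950] nm.
  Closed intervals match the printed bounds; on the 1-nm grid this
  leaves exactly 1,849 bands in three contiguous segments. All
  windowed operators (derivative, continuum hull) work per segment and
  never reach across a gap.
* **Nine transforms** (`apply_transform()`): raw R, 1/R, log10(1/R)
  (base 10 by the absorbance convention), first derivatives of each of
  those three, continuum removal, MSC, and peak normalization.
  Reflectance is floored at 1e-6 before reciprocal/log transforms so
  clipped synthetic values cannot produce infinities.
* **First derivative**: central finite differences per nm on the
  smoothed values, one-sided at segment edges. The derivative operator
  is applied after (not embedded in) the SG filter because smoothing
  and transformation are separate, ordered steps of the workflow; a
  per-nm (not per-index) denominator keeps units physical.
* **Continuum removal**: division by the upper convex hull of each
  segment (monotone-chain, anchored at segment endpoints); outputs lie
  in (0, 1] with exact 1 at hull touch points.
* **MSC**: per-sample regression on the calibration mean spectrum and
  inversion $(x - b)/a$. Validation spectra always use the calibration
  reference.
* **Normalization**: the cited sources do not print a formula, so the
  package uses per-sample peak normalization (divide by the sample's
  maximum), which preserves the curve shape and band rank order —
  consistent with the observation that the normalized curves keep the
  basic features of the raw spectra. This is an implementation choice,
  exposed as its own function.

## PLSR, cross-validation and VIP

`fit_plsr()` implements single-response NIPALS on mean-centered data.
Centering only, no variance scaling: all bands share reflectance units,
and autoscaling would inflate noise-dominated bands; the choice is
configurable by preprocessing the matrix. For one response the NIPALS
weights need no inner iteration; weight vectors have unit norm, and
$P'W$ is unit upper-triangular so coefficients follow by backsolve. At
full rank PLSR reproduces ordinary least squares — a test asserts this.

`loocv_rmse_curve()` refits the model from scratch (fresh centering)
for every left-out sample and every LV count 1..A_max. No closed-form
LOOCV shortcut is used for PLSR — the curve is defined by the
brute-force loop and tested against an independent re-implementation.
A_max defaults to min(20, n − 2, p). The LV count is the global
minimum of RMSE_CV, ties resolved toward fewer LVs (parsimony). The
alternative reading of the stopping description — the point where the
curve flattens — is available as a one-standard-error rule
(`rule = "onese"`), off by default because the minimum rule is the
primary printed criterion.

`vip_scores()` computes
$\mathrm{VIP}_j = \sqrt{p \sum_m w_{mj}^2 SS_m / \sum_m SS_m}$ with
$SS_m = q_m^2 t_m' t_m$ the explained response sum of squares of LV
$m$. The identity $\sum_j \mathrm{VIP}_j^2 = p$ holds algebraically,
so a VIP > 1 screen is non-empty for any non-degenerate model.

## Band selection

The initial screen `screen_b_vip()` keeps a band if VIP > 1 **or**
|B| exceeds the mean absolute B-coefficient — the union rule, following
the study's "or" wording. The four combined methods operate strictly on
the screened candidate set, so every combined result is a subset of the
screen.

* **Stepwise regression** (`stepwise_select()`): bidirectional, enter
  at partial-F p < 0.01, remove at p ≥ 0.05, deterministic, ties to
  the lowest wavelength, near-singular candidates skipped with a log
  entry. The F-tests are the standard OLS partial F (the original SPSS
  procedure is not specified beyond the thresholds); a test matches
  the full trajectory against `add1()`/`drop1()`.
* **SPA** (`spa_select()`): chains from *every* candidate start (no
  single-start heuristic), each step adding the band with the largest
  norm after projection onto the orthogonal complement of the chain;
  chains of size 1..min(30, n − 2) are scored by LOOCV RMSE of a
  multiple linear regression. The LOOCV uses the exact PRESS identity
  $e_i/(1-h_{ii})$, proven equal to the brute-force refit loop in a
  dedicated test.
* **Random frog** (`random_frog_select()`): phase 1 is a seeded
  reversible-jump style subset search (resize ~ round(N(|S|, 0.3|S|)),
  grow with random bands, shrink to the largest-|b| members, equal-size
  proposals swap one member; accept on improvement, else with
  probability RMSE_old/RMSE_new), tallying per-band selection
  frequencies over 1,000 iterations (the main runtime knob; the
  original formulation leaves all hyperparameters open). Phase 2 ranks
  bands by frequency and returns the ranked prefix minimizing LOOCV
  RMSE of a PLS model whose LV count is chosen by inner LOOCV. Prefix
  evaluation stops after 30 consecutive prefixes without improvement:
  the curve is convex-ish in practice and the exhaustive scan over
  several hundred prefixes would spend minutes confirming an incumbent
  minimum that an honest early stop identifies identically in the
  tested regimes. The initial subset size is the screening model's LV
  count.
* **UVE** (`uve_select()`): appends a same-size standard-normal noise
  block scaled to 1e-10 of the mean absolute signal (the scale cancels
  in the stability statistic), collects per-leave-out B-coefficients,
  and retains bands whose |mean/sd| exceeds the largest absolute
  stability among the noise columns. The augmented model's LV count is
  the screening model's LV count, the classical protocol. The
  alternative — re-choosing the LV count by LOOCV on the augmented
  matrix — is implemented (`n_lv = NULL`) but not used by the
  pipeline: on the default scene it selects about five LVs, the
  per-band coefficients overfit, and only one to three bands survive
  the max-noise threshold, which contradicts the expected behaviour of
  a selector whose output should still support a model close to the
  full-spectrum fit.

## Evaluation

`evaluate_predictions()` computes $R^2 = 1 - SSE/SST$, RMSE with the
evaluated dataset's size in the denominator, and
RPIQ $= (Q_3 - Q_1)/\mathrm{RMSE}$ using linear-interpolation
quartiles (`quantile` type 7 — the convention is not printed, so the
common default is used and recorded in every report). Categories:
RPIQ in [2.02, 2.70) poor, [2.70, 3.37) quantitative, [3.37, 4.05]
good, > 4.05 excellent; values below 2.02 are flagged `below-poor`.
Boundary values are assigned lower-inclusively; the prose is ambiguous
at the endpoints and the choice is asserted bit-exactly in tests.
A perfect fit (RMSE 0) reports a flagged infinite RPIQ rather than an
error.

## Numerical and degenerate-input choices

* Constant response: coefficients 0, intercept = mean, no error.
* Deflation to zero mid-fit: the model truncates with a warning.
* Zero-variance bands in correlation curves: r = 0 plus a flag.
* Zero coefficient spread in UVE: signed-infinite stability, band kept.
* Argmin ties everywhere resolve to fewer LVs / lower wavelengths.
* Hull touch points are clamped to exactly 1 against FP overshoot.
* All stochastic stages derive their seeds from one configuration seed
  (data: seed, seed + 2; random frog: seed + 4; UVE: seed + 5), making
  `run_all()` byte-reproducible.

## Problem sizes used by the test-suite

Unit tests run on small matrices (n = 8–40, p = 4–50) where brute-force
oracles are exact and fast. Pipeline tests run the full two-season
study on a 5-nm grid with three transforms and a 120-iteration random
frog — the same code paths at a size chosen to keep the default test
run short. The acceptance-style checks (screen reductions, planted-band
recovery) run the full 1-nm, 150-sample study over five seeds with the
default 1,000-iteration random frog, matching the configuration the
acceptance script reports on.

## Known limitations

* The scene is phenomenological; absolute R²/RMSE/RPIQ values on it do
  not transfer to field data, and the validation-season degradation
  observed with real spectra (cultivar and season shift) is only
  partially emulated by the different treatment structure of season
  two.
* PLS1 only; multi-response PLS, kernel/sparse/orthogonal variants are
  out of scope.
* Scatter correction beyond MSC (SNV, detrending) and wavelet-type
  preprocessing are out of scope.
* Stepwise regression inherits the usual caveats of data-driven
  variable selection (p-values are not corrected for selection).
* Random frog frequencies depend on the proposal distribution; with
  very small candidate sets (tens of bands) the phase-2 prefix can be
  short and unstable across seeds.
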