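---
title: "Methods: snow-referenced albedo and thermal-difference modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: snow-referenced albedo and thermal-difference modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bovitherm)
```

## The problem

Free-roaming cattle on open winter rangeland have almost no shade or
shelter, so the radiative balance of the hide is a first-order driver of
thermal stress. Two phenotype-linked quantities summarize that balance:

* the **hide albedo** — the fraction of incident solar radiation the coat
  reflects (0 = perfect absorber, 1 = perfect reflector); and
* **ΔT**, the signed difference between the animal's external surface
  temperature and ambient air temperature
  (`delta_t = temp_cow - temp_amb`).

ΔT enters the classical heat-transfer relations directly: forced convection
is `Q = h_c A ΔT`, the convective coefficient scales as
`h_c = c V^k1 / D^k2` with wind speed `V` and body dimension `D`, and net
long-wave exchange is `Q_n = A ε σ (T_o^4 − T_e^4)`. These are provided as
standalone calculators (`forced_convection()`,
`surface_heat_transfer_coefficient()`, `net_radiation()`); they frame the
regression results but are deliberately not coupled into them. The
exponents `k1`, `k2` bundle boundary-layer thermal properties that are
rarely measured for a live animal, so they are required user inputs with no
defaults asserted; the radiation law takes Kelvin only (`celsius_to_kelvin()`
is the helper), because the fourth-power law is meaningless on the Celsius
scale. The default emissivity 0.93 matches the infrared-thermometer setting
used for hide surfaces.

## Snow-referenced albedo estimation

A winter photograph that contains both animals and fresh snow carries its
own calibration target. With 8-bit gray values, the estimator is

* `albedo_rel = bright_cow / bright_snow`, the ratio of mean region gray
  values (`relative_albedo()`), and
* `albedo_abs = albedo_rel × 0.85`, rescaling by the assumed albedo of
  fresh snow (`absolute_albedo()`).

`pixel_summary()` computes region means, SDs and 256-bin gray histograms
over label-mask regions; `estimate_image_albedos()` applies the two
formulas to every non-snow region. Ratios above 1 are flagged and kept,
not clipped — they are diagnostically useful (wet hides, specular
highlights). The RGB-to-gray rule is the unweighted channel mean rounded
half-up, configurable to Rec. 601 luminance weights; common imaging tools
use either, and the choice is recorded in the pipeline configuration.

Replicate images are summarized per color by `summarize_replicates()`
(mean and SD/√k), and `compare_albedo_groups()` runs the comparison chain:
arcsine-square-root transform (the standard variance-stabilizing form for
proportions), Shapiro–Wilk on pooled within-color residuals, Kruskal–Wallis
across colors, then the ordered one-sided contrasts (white > red,
red > black, white > black) with exact Wilcoxon rank-sum p-values and
Cohen's d. Exact Wilcoxon is used because albedo replication is tiny
(three images); at n = 3 vs 3 the smallest attainable one-sided p is
exactly 0.05, so "significant at α" is evaluated as p ≤ α — otherwise no
separation could ever be declared at the study's own replication level.
Cohen's d defaults to the raw albedo scale (configurable to the transformed
scale). Significance letters are the connected components of the graph
joining colors whose contrast does not separate them; with three groups
this is equivalent to the usual compact letter display.

## The synthetic scene generator

No raw field images are distributed with the package, so
`generate_winter_image()` builds ground-truth scenes: a snow field at a
base gray level, rectangular hide patches whose expected gray follows the
linear brightness model `gray = base_gray × albedo / 0.85`, optional
multiplicative snow shadows, and additive Gaussian pixel noise, quantized
half-up to 8-bit. The linear brightness model is the unique one under
which the ratio estimator above is unbiased, which is exactly what a
ground-truth generator should provide. The default base gray of 170 sits
inside the observed snow gray range (135–250) and makes the three default
hide albedos (0.69, 0.16, 0.04) land on integer gray levels (138, 32, 8),
so noise-free recovery is exact to machine precision rather than limited
by quantization. Patches may not overlap and may not be brighter than the
snow reference; violations are rejected at specification time.

What the generator does *not* emulate: cow-shaped regions, shadow
gradients, specular reflection, vignetting, or summer coats (the
snow-referenced method is winter-only by construction). Passing tests
therefore demonstrate correctness of the estimator on images satisfying
its own brightness model, not robustness to real-photograph artifacts.

## The synthetic thermal generator

`generate_thermal_observations()` emulates the 638-record field campaign:
hide colors in proportions 183/158/297 (white/red/black), each color
carrying its measured albedo, ambient temperature spanning −32.8 to
35.6 °C, and eight daily weather/radiation covariates with the marginal
ranges and means of the field summary table. Marginals are scaled beta
distributions (concentration 4) so both the declared range and the declared
mean are respected; correlated covariates are produced by a Gaussian copula
with latent correlation 0.85 for the three declared high-correlation pairs
(earth-skin temperature with each radiation flux; humidity with wind; VPD
with dewpoint), which yields sample Pearson correlations ≈ 0.82 after the
marginal transform — comfortably above the 0.7 pruning threshold. The
latent correlation between the two radiation fluxes is 0.6: they must
co-vary (both are driven by earth-skin temperature, and positive
definiteness requires ≥ 0.445) but must stay below the pruning threshold so
that only the earth-skin variable is removed, as in the field analysis.
Each observation carries its own integer date index with one covariate row
per date; daily replication structure is not simulated (the field analysis
itself fitted no repeated-measures structure).

Two generation modes serve two different downstream analyses:

* **model mode** draws the surface temperature from
  `temp_cow = b0 + 0.1770 temp_amb + 19.172 ktclear − 27.026 albedo + ε`,
  ε ~ N(0, 5 °C). The intercept is not a published quantity; it is derived
  once, at parameter construction, from the identity
  `mean response = β · mean covariates` using the declared covariate means
  and the color-weighted mean albedo, giving b0 ≈ 27.04 so that the mean
  surface temperature is 32.4 °C. ΔT is then `temp_cow − temp_amb`, which
  makes the ΔT regression's ambient coefficient equal the surface model's
  coefficient minus one (0.1770 − 1 = −0.8230) — an exact structural
  identity the tests verify.
* **slope mode** draws ΔT directly from per-color lines with slopes −0.45
  (white), −0.92 (red) and −1.07 (black). The per-color intercepts are not
  recoverable from published summaries (the printed stratified means equal
  their own range maxima, an internal inconsistency), so they were fixed
  once at 25/30/35 °C: this yields an overall mean ΔT ≈ 28 °C at the mean
  ambient temperature and a ~2× black-to-white ΔT ratio at the coldest
  temperatures, matching the qualitative pattern the slopes imply.

All randomness flows from one integer seed; identical parameters and seed
reproduce bit-identical tables and images.

## ΔT modeling and staged AICc selection

`assemble_dataset()` joins observations to daily covariates by date
(erroring on missing dates). `prune_correlated()` then removes, within
each measurement-source group, one member of every pair with |Pearson r|
above 0.7. Because the field analysis states outcomes rather than a rule,
removal is governed by an explicit drop-preference list (default:
earth-skin temperature, humidity, VPD — reproducing the three removals) and
errors when the list is silent on a flagged pair, rather than guessing.
The procedure iterates until stable, so it is idempotent. The response
variables are excluded: they are not candidate predictors of themselves.
The default source grouping pools the station and interpolated weather
products into one group, since the dewpoint–VPD removal crosses the
station/interpolation boundary.

`fit_ols()` wraps a Gaussian linear fit and records the quantities
selection needs, with the parameter-count convention
K = slopes + intercept + residual variance (null model K = 2).
`aicc()` is `−2 logLik + 2K + 2K(K+1)/(n−K−1)`; `akaike_weights()`
computes ΔAICc and normalized weights. `staged_selection()` runs the
three-step procedure: step 1 ranks single weather variables
(ambient, dewpoint, wind — humidity having been pruned), step 2 single
radiation variables (clear-sky insolation index and the two fluxes),
step 3 the nested combinations of the two step winners plus animal
attributes (albedo, and the surface temperature itself when the response is
ΔT). A null model is included in every step; models within 2 AICc of the
step's best form the top set; AICc ties break by parsimony then
lexicographic term order so selection is deterministic. The step winner
carried forward is the best-ranked single-term model (the null can occupy
the top set but carries no term). The final model's coefficients are
screened by 95% confidence interval, "informative" meaning the interval
excludes zero.

One structural consequence worth knowing: because ΔT is an exact linear
combination of surface and ambient temperature, the ΔT model containing
both predictors fits perfectly (residual variance at machine epsilon), and
its AICc is an enormous negative number. The generator reproduces this
honestly — it is a property of using ΔT as a response alongside its own
components, not an artifact.

## Per-color slopes and ANCOVA

`fit_color_regressions()` fits ΔT on ambient temperature separately per
color, reporting slope, intercept, r², the two-sided slope p-value and the
residual SD; `predict_band()` gives the standard 95% out-of-sample
prediction interval, narrowest at the predictor mean. `ancova_slopes()`
fits the interaction model `delta_t ~ temp_amb * color`, tests the
slope-heterogeneity block with an F-test, and compares all pairwise slope
differences with Tukey-adjusted p-values on the interaction contrasts (the
contrast family is all pairwise slope differences). By the algebra of the
saturated interaction coding, the stratified slopes equal the interaction
model's per-color slopes exactly — a tested invariant. A median-centered
(Brown–Forsythe) Levene test and a Kruskal–Wallis test on ΔT by color are
attached, since unequal variances across colors are expected by design
(steeper slopes spread ΔT further).

## Numerical and design choices

* Rounding of gray values is half-up, not banker's, so 0.5 always
  brightens; tests pin this.
* ΔT is signed, despite sometimes being described as an absolute
  difference: the observed minima are negative and the slopes against
  ambient temperature are negative, neither of which survives an absolute
  value.
* `fit_ols()` accepts n = K (one residual df) so small worked examples are
  fittable; AICc is reported as `NA` when n ≤ K + 1 rather than erroring.
* Rank-deficient designs and overlapping scene patches are rejected, not
  silently repaired.
* Statistical primitives with canonical implementations (Shapiro–Wilk,
  Kruskal–Wallis, Levene, Tukey-adjusted contrasts) delegate to the
  standard routines; the test suite cross-checks the wrapped
  Kruskal–Wallis and the pixel summaries against independent brute-force
  implementations.

## Problem sizes used in the tests

The recovery suites run at the study's own scale: staged selection at
n = 638 over 100 seeds, coefficient-coverage at n = 638 over 200 seeds,
slope recovery at 200 observations per color over 100 seeds, albedo
round-trips on 160×120-pixel scenes. These sizes keep the full suite in
the tens of seconds while leaving the Monte Carlo margins interpretable.

## Known limitations

* The albedo estimator inherits every limitation of the brightness model:
  it is winter-only, assumes the snow reference is unshadowed and
  constant-albedo, and has no shadow correction or automatic segmentation —
  masks are taken as given.
* The copula/beta covariate model reproduces ranges, means and the declared
  correlation pairs, nothing more; it is a stand-in, not an inference about
  the joint weather distribution.
* Published real-data coefficient values and AICc magnitudes are not
  reproduction targets: the underlying field data are not distributed, and
  several printed summaries are internally inconsistent (stratified ΔT
  means equal to range maxima; two different p-values for the same albedo
  test; effect sizes not recoverable from printed means and SEs).
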