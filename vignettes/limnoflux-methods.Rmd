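---
title: "Reconstructing sediment fluxes under age-model uncertainty: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing sediment fluxes under age-model uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Lake sediments archive the history of carbon burial and catchment erosion,
but every quantity derived from a core inherits the uncertainty of its
age-depth model. `limnoflux` implements a complete chain from dated
horizons to flux time series and their downstream statistics, carrying a
posterior *ensemble* of chronologies through every step instead of a
single best-fit age model.

The core quantities are mass accumulation fluxes,

\[
\mathrm{TOC}_{flux} = \rho \cdot \mathrm{SR} \cdot \frac{\%\mathrm{TOC}}{100}\cdot 10^4,
\qquad
\mathrm{L}_{flux} = \rho \cdot \mathrm{SR} \cdot \frac{100 - \%\mathrm{TOC} - \%\mathrm{TIC}}{100}\cdot 10^4,
\]

with dry bulk density \(\rho\) in g cm\(^{-3}\), linear sedimentation rate
SR in cm yr\(^{-1}\), and fluxes in g m\(^{-2}\) yr\(^{-1}\). The
\(10^4\) factor converts g cm\(^{-2}\) yr\(^{-1}\) to
g m\(^{-2}\) yr\(^{-1}\); it is stated explicitly and unit-tested because
flux magnitudes are meaningless without it. Compositional closure uses
the calcite stoichiometry \(\%\mathrm{carb} = 100.09\,\mathrm{TIC}/12.01\)
and the Van Bemmelen factor \(\%\mathrm{OM} = 1.724\,\mathrm{TOC}\);
silicates close the sum to 100. A negative silicate balance (possible in
organic-rich sediments with a fixed 1.724) is clipped to zero and
flagged rather than treated as an error.

## The age-depth model

`fit_age_model()` is a Bacon-style Bayesian accumulation model. The core
is divided into equal sections; per-section accumulation *times*
\(a_i\) (yr cm\(^{-1}\)) follow

\[
a_1 = g_1,\qquad a_i = w\,a_{i-1} + (1-w)\,g_i,\qquad
g_i \sim \Gamma(\alpha,\ \alpha/\mu_a),
\]

with memory \(w \sim \mathrm{Beta}\) (mean/strength parameterization).
Because every \(a_i > 0\), each posterior draw is a monotone age-depth
function by construction — a violated member is a bug, never a warning.
Dates enter a Student-t likelihood (default 6 df), which makes single
outlying dates (including mild stratigraphic reversals) soft rather than
fatal; reversals between calendar dates beyond 5 combined sigma are
rejected as data errors. Radiocarbon dates are compared in conventional
¹⁴C space through the calibration curve, with the curve error added in
quadrature — calibrating inside the likelihood would double-count the
curve uncertainty, so `calibrate_date()` exists only for display and
fixtures. Lead-210 and cesium-137 results are ingested as calendar dates
with errors; CRS modelling of raw activities is out of scope.

Sampling is adaptive Metropolis-within-Gibbs on (top age, log
accumulations, logit memory), targeting 20–45% acceptance. Defaults
(5 cm sections, gamma shape 1.5, memory mean 0.7 / strength 4, 60,000
iterations thinned to 1,000 members) mirror customary practice; tests
and the bundled fixtures use far fewer iterations because parameter
*recovery*, not chain length, is what they assert. Convergence is
screened by a split-chain potential-scale-reduction statistic on the
mean age; values above 1.1 set a diagnostic flag (not an exception).
With no usable dates the function samples the prior directly, which is
also how the prior-mean recovery test works. Event layers
(instantaneous deposits such as turbidites) can be listed as excluded
depth intervals: they are collapsed before modelling and re-expanded
with flat age across the layer.

The per-sample sedimentation rate attached by `compute_fluxes()` is the
interval rate between midpoints towards the neighbouring samples
(centred), which is stable for unevenly spaced samples; a point-slope
from the section the sample happens to fall in would jump at section
boundaries.

## Change-point detection

Two deliberately different procedures are provided.

**CumSum.** \(C_k=\sum_{i\le k}(x_i-\bar x)\); its terminal value is
zero by algebra (used as a self-check). Slope-sign changes of \(C\)
separate above-mean from below-mean phases. The paper-level description
is qualitative, so significance is formalized here: candidates are found
by recursive chord-deviation segmentation of the curve (the principal
extremum of each segment), and accepted when both flanks hold at least
`min_segment` points (default 5) and the least-squares slope change
exceeds `slope_delta_min` (default 0.1) times the curve-range/time-span
scale. Raw local extrema are *not* used as flank anchors: on a noisy
series every wiggle is an extremum and all flanks collapse below
`min_segment`. Change-point time is the midpoint between the flanking
samples; unevenly spaced times are used as-is.

**GAM first derivative.** A penalized cubic regression spline is fitted
on calendar time (smoothing by GCV, optionally REML). The first
derivative is evaluated by central finite differences of the spline
basis on a 2001-point grid, and a *simultaneous* confidence band is
formed from the max-|t| statistic over draws from the Bayesian
coefficient covariance. Grid runs where the band excludes zero (at
least 2 grid steps long; shorter runs are numerical noise) are the
significant-change intervals. The default basis dimension is
`max(10, min(30, floor(n/2)))` rather than a fixed 10: with 38–83
points spanning a millennium, a 10-dimensional basis saturates (EDF
pinned at k−1) and smears decadal steps by ~25 years; a generous basis
with the penalty controlling smoothness is standard mgcv practice, and
the white-noise false-positive rate of the simultaneous band was
re-verified (≈ 3–7% at the 95% level) after the change. The "principal"
change point reported for a GAM result is the steepest point of the
trend inside the significant interval with the largest net fitted
change — the interval centre is biased for asymmetric rises, and the
globally steepest point can sit in a short noise interval.

Both methods run by default on the ensemble-median series of a flux
ensemble; per-member mode returns the distribution of principal change
times instead. Neither interpolates onto a regular grid.

## Ordination

* `standardized_pca()` — SVD on centred (optionally unit-variance)
  data; zero-variance columns are dropped with a notice.
* `hellinger_pca()` — taxa are kept when their maximum relative
  abundance exceeds 1% *and* they occur in ≥ 2 samples (the filter
  wording in the source material is ambiguous between "max over
  samples" and "average"; max is implemented because an average-based
  rule would delete taxa that bloom in a single interval, precisely the
  signal of interest). Retained counts are re-closed per sample, square-
  root transformed, and analysed by centred, non-standardized PCA.
* `ppca_missing()` — EM for the probabilistic PCA model with isotropic
  noise, missing cells integrated out of the observed-data likelihood.
  It is initialized at the eigendecomposition of the mean-imputed
  covariance with the 1/n denominator, which is the exact ML solution
  for complete data, so the complete-data case agrees with classical
  PCA to numerical precision rather than to EM tolerance.
* `age_uncertain_pca()` — for each ensemble draw, every variable is
  averaged onto a common time grid (default 25-yr bins over
  800–2015 CE; no width is inherited from the source material, so it is
  a config knob), standardized within the draw, and decomposed by PPCA
  with empty bins treated as missing. Component signs are aligned to
  the first draw's loadings by dot-product sign, making the summary
  invariant to per-member sign flips. Per-bin score distributions are
  summarized by the median and 50%/95% highest-density regions
  (shortest-interval estimator).

## The synthetic world

`simulate_transect()` builds multi-lake cores with known truth. What it
states, and why:

* **Chronology**: the generator mirrors the age model's own gamma/memory
  form, plus a compaction gradient (bottom/top accumulation-time ratio
  3): recent, uncompacted mud accumulates more centimetres per year, so
  the last two centuries are sampled at the high time resolution real
  cores show. Core-average accumulation ~10 yr cm\(^{-1}\) over 120 cm
  gives the ~1200-yr span and 60 samples at 2-cm spacing (within the
  38–83 range of the emulated records).
* **Dating**: a lead-210/cesium-137-style calendar ladder over the last
  ~160 years with errors growing from ±2 to ±10 yr, then four AMS ¹⁴C
  dates (±30 yr) down to the core base. Leaving the basal metres
  undated produces prior-driven sedimentation rates — and spurious
  deep-time flux artefacts — which is why the deepest date sits near
  the bottom.
* **Regimes**: lithogenic flux steps at 1850 CE, organic (TOC-flux)
  steps at 1950 CE with per-lake magnitudes spanning the reported field
  ranges (e.g. 14 → 66 g m\(^{-2}\) yr\(^{-1}\)), a ramped
  δ¹³C decline of 1–6‰ from 1850, and a C/N decline after 1950. Flux
  noise is proportional to the regime level (10%) so lakes of different
  magnitude carry comparable relative scatter. Flux-level regimes are
  inverted through the true sedimentation rate and density into TOC/TIC
  percentages, so the *reconstructed* flux carries the configured step
  and closure (lithogenic fraction in [0, 100]) holds by construction.
* **Diatoms**: Dirichlet–multinomial counts (400 valves/sample) whose
  planktonic share ramps from 0.15 to 0.6 after 1950, with chrysophyte
  cysts and a microsphere spike.

What the generator does **not** emulate: varves, XRF-scanner signals,
raw ²¹⁰Pb activity profiles, taphonomic dissolution of diatoms,
within-lake spatial heterogeneity, and compaction of the *proxy values*
themselves. A green end-to-end test therefore establishes that the
pipeline recovers changes of the stated shape and magnitude under
realistic dating noise — not that any particular field inference is
correct.

All randomness flows from explicit seeds; pipeline stages derive their
seeds from one master seed so that a run is reproducible end to end.

## Numerical choices and degenerate inputs

* Calibration densities are normalized by the trapezoid rule on the
  curve grid; a date outside the curve span ±5σ is a calibration error.
* Proposal scales adapt only during burn-in (every 50 iterations,
  log-scale update towards 30% acceptance), so the post-burn-in chain
  is a valid fixed-kernel sampler.
* Ties: two dates at the same depth are kept as independent likelihood
  terms. Duplicate *times* in a GAM series are an error (the trend is a
  function of time).
* PPCA guards: every row and column must have an observed cell;
  non-convergence in `max_iter` is an error carrying the likelihood
  trace; the coefficient covariance for GAM derivative draws is checked
  for positive semi-definiteness (heavily penalized directions give
  legitimately tiny eigenvalues and are clamped, not rejected).
* CumSum on a constant series returns no change points (the curve is
  identically zero), not an error.

## Known limitations

* The MCMC is single-chain (split-half diagnostics only) and pure R;
  very long cores with many sections would benefit from a compiled
  sampler.
* The GAM assumes independent Gaussian errors; AR(1) proxy noise
  inflates the false-positive rate of the derivative band somewhat, as
  it does for every trend-fitting method applied to autocorrelated
  series.
* Sediment-trap utilities implement the arithmetic only; trap geometry
  corrections (focusing, resuspension) are out of scope.
* The age-uncertain PCA standardizes within each draw; variables with
  draw-dependent observation windows therefore contribute slightly
  different effective weights per draw.
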