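# limnoflux

Reconstruction of organic-carbon and lithogenic fluxes from dated
lake-sediment cores, with the age-model uncertainty propagated through
every downstream statistic.

## Who this is for

Paleolimnologists and paleoecologists who have (i) a table of dated
horizons per core (radiocarbon, lead-210/cesium-137-derived calendar
dates, known events), (ii) depth-resolved geochemistry (TOC, TIC,
δ¹³C\_OM, C/N, dry bulk density, grain size), and optionally (iii)
diatom valve counts — and who want flux time series, regime-shift
detection, and ordination that honestly carry chronological
uncertainty instead of a single best-fit age model.

## What it computes

* **Bayesian age-depth model** (`fit_age_model`): gamma-distributed
  section accumulation times with first-order memory,
  `a_i = w a_{i-1} + (1-w) g_i`, `g_i ~ Γ(α, α/μ_a)`, Student-t dating
  likelihood (radiocarbon compared in ¹⁴C space through the calibration
  curve), adaptive Metropolis-within-Gibbs. Output is a posterior
  ensemble of monotone age-depth functions.
* **Fluxes per ensemble member** (`compute_fluxes`):
  `TOC_flux = ρ · SR · (%TOC/100) · 10⁴` and
  `L_flux = ρ · SR · ((100 − %TOC − %TIC)/100) · 10⁴` in g m⁻² yr⁻¹,
  plus the stoichiometric closure
  `%carbonates = 100.09·TIC/12.01`, `%OM = 1.724·TOC`,
  silicates as remainder (`composition_closure`), time binning with
  median and quantile bands, and sediment-trap utilities.
* **Change points**: cumulative sum of deviations from the mean with
  slope-sign-change candidates and formalized significance
  (`cumsum_changepoints`), and a penalized-spline trend whose
  *simultaneous* confidence band on the first derivative defines
  significant-change intervals (`fit_gam_trend`,
  `derivative_changepoints`).
* **Ordination**: standardized/compositional PCA, Hellinger-transformed
  diatom PCA with the >1% / ≥2-occurrences taxon filter, probabilistic
  PCA with missing values by EM (`ppca_missing`), and an age-uncertain
  ensemble PCA that bins every variable per chronology draw and
  summarizes scores by median and 50%/95% highest-density regions
  (`age_uncertain_pca`).
* **Synthetic cores with known truth** (`simulate_transect` and
  friends): multi-lake fixtures with a lithogenic flux step at 1850 CE,
  an organic step at 1950 CE, δ¹³C declines of 1–6‰ and decreasing C/N,
  so every stage has a parameter-recovery test.
* **Pipeline** (`run_pipeline` + the CLI at `inst/cli/limnoflux.R`):
  config-driven end-to-end run, deterministic given (config, seed),
  per-lake error quarantine, provenance headers on every output table.

## Worked example

```r
library(limnoflux)

# a synthetic core with known truth: lithogenic step at 1850 CE,
# organic (TOC-flux) step at 1950 CE
core <- simulate_transect(n_lakes = 1, seed = 101)$lake01

curve <- synthetic_calibration_curve()
ens <- fit_age_model(core$dates, curve,
                     age_model_settings(n_iter = 2500, burn_in = 600,
                                        n_members = 200),
                     seed = 11, core_depth = 120)
head(ensemble_summary(ens, units = "CE"), 3)
#>   depth   median     q2.5    q97.5
#> 1     0 2016.857 2009.739 2023.426
#> 2     5 1997.869 1993.222 2003.288
#> 3    10 1976.970 1970.887 1984.689

fe <- compute_fluxes(core$proxies, ens)
tail(flux_band_summary(bin_flux_ensemble(fe, 25, 1800, 2015, "toc_flux")), 3)
#>   bin_centre   median      q25      q75     q2.5     q97.5
#> 7     1962.5 65.68612 59.78569 70.43589 47.54468  82.24928
#> 8     1987.5 61.76683 55.88024 67.87552 45.46673  81.26323
#> 9     2012.5 59.90759 53.48371 70.61432 43.92610 111.83149

cp <- detect_changepoints(median_flux_series(fe, "toc_flux"), seed = 12)
cp$cumsum
#>   method  cp_time sign_change slope_before slope_after n_before n_after
#> 1 cumsum 1941.119           1   -0.4139044    4.956964       51      10
principal_cp(cp$gam)
#> [1] 1940.205
```

Reading the output: the chronology's core top is ~2017 CE (collection
2015 ± dating noise); the post-1950 TOC flux band sits at ~60–66
g m⁻² yr⁻¹ (the fixture's configured step is 14 → 66, placed at 1950);
both change-point methods put the principal organic regime shift at
~1940–1941, within a decade of the true step year — the residual offset
is the honest chronological uncertainty of the dated horizons.

## Documentation

The methods vignette (`vignettes/limnoflux-methods.Rmd`) describes the
model and its assumptions, every tunable parameter with units and
defaults, what the synthetic generator does and does not emulate, and
the numerical choices (tolerances, initialization, tie-breaks,
degenerate inputs).
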