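## Synthetic sediment cores with known ground truth.
##
## The generator mirrors the generative form of the age model itself
## (gamma-distributed section accumulations with first-order memory), so
## every downstream stage -- chronology fitting, flux reconstruction,
## change-point detection, ordination -- has a parameter-recovery target.

#' Simulate a true (piecewise-linear) age-depth chronology
#'
#' Section accumulation rates (yr cm^-1) follow a first-order gamma mixture:
#' `a_1 ~ Gamma(shape, mean = acc_mean)` and
#' `a_i = memory * a_{i-1} + (1 - memory) * g_i`, `g_i ~ Gamma(shape, mean = acc_mean)`.
#' Age increases strictly downward; internally ages are stored as years
#' before core collection, reported as calendar years CE.
#'
#' @param n_sections number of equal-thickness sections (>= 1).
#' @param thickness section thickness, cm.
#' @param acc_mean prior mean accumulation, yr cm^-1.
#' @param acc_shape gamma shape of the accumulation innovations.
#' @param memory autocorrelation of successive sections, in [0, 1].
#' @param top_age calendar year CE at depth 0.
#' @param collection_year year CE the core was collected (time datum).
#' @param compaction bottom-to-top ratio of the mean accumulation time
#'   (yr cm^-1). 1 = stationary; values > 1 emulate compaction (loose
#'   surface mud accumulates more cm per year, so recent decades occupy
#'   more depth and are sampled at higher time resolution, as in real
#'   cores). The core-average prior mean stays `acc_mean`.
#' @param seed RNG seed.
#' @return a `true_chronology`: section boundaries (cm), per-section
#'   accumulations (yr cm^-1), and ages at the boundaries.
#' @export
simulate_chronology <- function(n_sections, thickness, acc_mean,
                                acc_shape = 1.5, memory = 0.7,
                                top_age = 2015, collection_year = 2015,
                                compaction = 1, seed = NULL) {
  if (n_sections < 1 || thickness <= 0 || acc_mean <= 0 || acc_shape <= 0)
    abort("n_sections >= 1, thickness, acc_mean and acc_shape must be > 0",
          "limnoflux_parameter_error")
  if (memory < 0 || memory > 1)
    abort("memory must lie in [0, 1]", "limnoflux_parameter_error")
  if (compaction < 1)
    abort("compaction must be >= 1", "limnoflux_parameter_error")
  grad <- if (n_sections == 1L) 1 else
    seq(2 / (1 + compaction), 2 * compaction / (1 + compaction),
        length.out = n_sections)
  acc <- with_seed(seed, {
    g <- stats::rgamma(n_sections, shape = acc_shape,
                       rate = acc_shape / (acc_mean * grad))
    a <- numeric(n_sections)
    a[1] <- g[1]
    if (n_sections > 1)
      for (i in 2:n_sections) a[i] <- memory * a[i - 1] + (1 - memory) * g[i]
    a
  })
  boundaries <- seq(0, by = thickness, length.out = n_sections + 1L)
  yb_top <- collection_year - top_age      # years before collection at depth 0
  yb <- yb_top + c(0, cumsum(acc * thickness))
  structure(list(boundaries = boundaries, acc = acc,
                 top_age = top_age, collection_year = collection_year,
                 yb = yb),
            class = "true_chronology")
}

#' True age at depth(s) for a simulated chronology
#'
#' @param chron a `true_chronology`.
#' @param depths depths, cm.
#' @param units `"CE"` (calendar year) or `"yb"` (years before collection).
#' @export
chron_age <- function(chron, depths, units = c("CE", "yb")) {
  units <- match.arg(units)
  yb <- interp_strict(chron$boundaries, chron$yb, depths, what = "depth")
  if (units == "yb") yb else chron$collection_year - yb
}

#' True linear sedimentation rate at depth(s), cm yr^-1
#' @inheritParams chron_age
#' @export
chron_sed_rate <- function(chron, depths) {
  k <- pmin(pmax(findInterval(depths, chron$boundaries,
                              rightmost.closed = TRUE), 1L),
            length(chron$acc))
  1 / chron$acc[k]
}

#' Simulate dated horizons for a known chronology
#'
#' Calendar-type dates (lead-210-derived, cesium-137, known events) are drawn
#' `N(true age CE, error^2)`. Radiocarbon dates map the true calendar age
#' through the calibration curve into conventional 14C years and add
#' `N(0, error^2)` there.
#'
#' @param chron a `true_chronology`.
#' @param depths dated depths, cm (within the core).
#' @param errors 1-sigma errors, yr (> 0).
#' @param types `"calendar"` or `"radiocarbon"`, recycled.
#' @param curve `calibration_curve`; required when any type is radiocarbon.
#' @param seed RNG seed.
#' @return a `date_table` data frame: labID, age, error, depth, type.
#'   Radiocarbon ages are conventional 14C yr BP; others calendar yr CE.
#' @export
simulate_dates <- function(chron, depths, errors,
                           types = "calendar", curve = NULL, seed = NULL) {
  types <- rep_len(types, length(depths))
  errors <- rep_len(errors, length(depths))
  if (any(errors <= 0))
    abort("date errors must be > 0", "limnoflux_parameter_error")
  if (any(depths < min(chron$boundaries) | depths > max(chron$boundaries)))
    abort("dated depth outside the simulated core", "limnoflux_range_error")
  true_ce <- chron_age(chron, depths, "CE")
  with_seed(seed, {
    age <- numeric(length(depths))
    for (i in seq_along(depths)) {
      if (types[i] == "radiocarbon") {
        if (is.null(curve))
          abort("radiocarbon dates need a calibration curve",
                "limnoflux_parameter_error")
        cal_bp <- 1950 - true_ce[i]
        if (cal_bp < min(curve$cal_bp) || cal_bp > max(curve$cal_bp))
          abort("true age outside the calibration curve span",
                "limnoflux_range_error")
        mu <- stats::approx(curve$cal_bp, curve$c14_age, xout = cal_bp)$y
        age[i] <- mu + stats::rnorm(1, 0, errors[i])
      } else {
        age[i] <- true_ce[i] + stats::rnorm(1, 0, errors[i])
      }
    }
    date_table(labID = sprintf("sim-%02d", seq_along(depths)),
               age = age, error = errors, depth = depths, type = types)
  })
}

## Known proxy variables the regime machinery accepts. Flux-level names are
## translated to dry-mass percentages through the true chronology.
.proxy_vars <- c("TOC", "TIC", "d13C_OM", "CN", "density",
                 "sand", "silt", "clay", "BioSi", "chlorophyll",
                 "TOC_flux", "L_flux")

#' Specify one proxy regime (step or ramp change)
#'
#' @param variable proxy name; one of TOC, TIC, d13C_OM, CN, density, sand,
#'   silt, clay, BioSi, chlorophyll, or the flux-level targets TOC_flux /
#'   L_flux (g m^-2 yr^-1), which are converted to percentages using the
#'   true sedimentation rate and density.
#' @param change_year calendar year CE of the change.
#' @param shape `"step"` or `"ramp"`.
#' @param pre_level,post_level levels in the variable's units.
#' @param ramp_duration ramp length, yr (ignored for steps).
#' @param noise_sd marginal SD of the AR(1) noise (>= 0).
#' @param ar1 lag-1 autocorrelation of the noise, in [0, 1).
#' @export
regime <- function(variable, change_year, shape = c("step", "ramp"),
                   pre_level, post_level = pre_level,
                   ramp_duration = 20, noise_sd = 0, ar1 = 0) {
  shape <- match.arg(shape)
  if (!variable %in% .proxy_vars)
    abort(sprintf("unknown proxy variable '%s'", variable),
          "limnoflux_schema_error")
  if (noise_sd < 0 || ar1 < 0 || ar1 >= 1 || ramp_duration <= 0)
    abort("noise_sd >= 0, 0 <= ar1 < 1, ramp_duration > 0 required",
          "limnoflux_parameter_error")
  structure(list(variable = variable, change_year = change_year,
                 shape = shape, pre_level = pre_level,
                 post_level = post_level, ramp_duration = ramp_duration,
                 noise_sd = noise_sd, ar1 = ar1),
            class = "regime_spec")
}

## Regime mean curve at calendar times t (CE).
regime_mean <- function(r, t) {
  if (r$shape == "step") {
    ifelse(t >= r$change_year, r$post_level, r$pre_level)
  } else {
    f <- pmin(pmax((t - r$change_year) / r$ramp_duration, 0), 1)
    r$pre_level + f * (r$post_level - r$pre_level)
  }
}

## AR(1) noise with marginal SD `sd` and lag-1 correlation `phi`.
ar1_noise <- function(n, sd, phi) {
  if (sd == 0 || n == 0) return(numeric(n))
  e <- numeric(n)
  e[1] <- stats::rnorm(1, 0, sd)
  if (n > 1)
    for (i in 2:n) e[i] <- phi * e[i - 1] + stats::rnorm(1, 0, sd * sqrt(1 - phi^2))
  e
}

#' Default regimes emulating the post-1850 / post-1950 transect signal
#'
#' Step/ramp increases in TOC and lithogenic flux after 1850 and 1950 CE,
#' a ramped carbon-isotope decline, and a decreasing C/N ratio; magnitudes
#' follow the reported field ranges (e.g. a TOC flux step from 14 to
#' 66 g m^-2 yr^-1 around 1970, isotope declines of 1-6 per mil).
#'
#' @param toc_pre,toc_post TOC flux before/after the change, g m^-2 yr^-1.
#' @param toc_change_year year CE of the TOC flux step.
#' @param lith_pre,lith_post lithogenic flux levels, g m^-2 yr^-1.
#' @param d13c_decline total isotope decline, per mil (positive number).
#' @param noise_frac flux noise SD as a fraction of the mean regime level,
#'   so lakes with different flux magnitudes carry comparable relative
#'   scatter.
#' @export
default_regimes <- function(toc_pre = 14, toc_post = 66,
                            toc_change_year = 1970,
                            lith_pre = 150, lith_post = 300,
                            d13c_decline = 4, noise_frac = 0.1) {
  list(
    regime("TOC_flux", toc_change_year, "step", toc_pre, toc_post,
           noise_sd = noise_frac * (toc_pre + toc_post) / 2, ar1 = 0.3),
    regime("L_flux", 1850, "step", lith_pre, lith_post,
           noise_sd = noise_frac * (lith_pre + lith_post) / 2, ar1 = 0.3),
    regime("d13C_OM", 1850, "ramp", -24, -24 - d13c_decline,
           ramp_duration = 150, noise_sd = 0.3, ar1 = 0.3),
    regime("CN", 1950, "ramp", 12, 8, ramp_duration = 60,
           noise_sd = 0.5, ar1 = 0.3)
  )
}

#' Simulate a depth-resolved proxy record on a known chronology
#'
#' Each variable is its regime mean curve evaluated at the sample's true
#' age plus AR(1) Gaussian noise truncated to physical bounds (TOC, TIC,
#' grain-size fractions in [0, 100]; TOC + TIC <= 100; density > 0).
#' Flux-level regimes (`TOC_flux`, `L_flux`) are converted to dry-mass
#' percentages through the true sedimentation rate and the simulated dry
#' bulk density, so the implied flux series carries the configured regime.
#'
#' @param chron a `true_chronology`.
#' @param regimes list of [regime()] specs.
#' @param sample_spacing sampling interval, cm.
#' @param density_mean,density_sd,density_ar1 dry-bulk-density AR(1)
#'   parameters, g cm^-3 (used unless a `density` regime is given).
#' @param seed RNG seed.
#' @return a `proxy_record` data frame (depth + proxy columns) with the
#'   ground truth (true ages, regimes) in `attr(, "truth")`.
#' @export
simulate_proxies <- function(chron, regimes = default_regimes(),
                             sample_spacing = 1,
                             density_mean = 0.5, density_sd = 0.05,
                             density_ar1 = 0.5, seed = NULL) {
  vars <- vapply(regimes, function(r) r$variable, character(1))
  if (anyDuplicated(vars))
    abort("duplicate regime variables", "limnoflux_schema_error")
  depth_max <- max(chron$boundaries)
  depths <- seq(sample_spacing / 2, depth_max, by = sample_spacing)
  n <- length(depths)
  t_ce <- chron_age(chron, depths, "CE")
  sr <- chron_sed_rate(chron, depths)              # cm yr^-1

  with_seed(seed, {
    out <- list(depth = depths)
    # density first: flux->percent conversion needs it
    if ("density" %in% vars) {
      r <- regimes[[match("density", vars)]]
      dens <- regime_mean(r, t_ce) + ar1_noise(n, r$noise_sd, r$ar1)
    } else {
      dens <- density_mean + ar1_noise(n, density_sd, density_ar1)
    }
    dens <- pmax(dens, 0.05)
    out$density <- dens

    pct <- list()  # percent-space series to close later
    for (r in regimes) {
      if (r$variable == "density") next
      m <- regime_mean(r, t_ce) + ar1_noise(n, r$noise_sd, r$ar1)
      if (r$variable == "TOC_flux") {
        pct$TOC <- pmax(m, 0) / (dens * sr * 1e4) * 100
      } else if (r$variable == "L_flux") {
        pct$lith <- pmax(m, 0) / (dens * sr * 1e4) * 100
      } else if (r$variable %in% c("TOC", "TIC")) {
        pct[[r$variable]] <- pmin(pmax(m, 0), 100)
      } else if (r$variable %in% c("sand", "silt", "clay", "BioSi")) {
        out[[r$variable]] <- pmin(pmax(m, 0), 100)
      } else if (r$variable == "chlorophyll") {
        out[[r$variable]] <- pmax(m, 0)
      } else {
        out[[r$variable]] <- m
      }
    }
    # close TOC/TIC so the lithogenic fraction stays in [0, 100]
    toc <- if (!is.null(pct$TOC)) pct$TOC else rep(0, n)
    tic <- if (!is.null(pct$TIC)) pct$TIC else rep(0, n)
    if (!is.null(pct$lith)) {
      lith <- pmin(pmax(pct$lith, 0), 100)
      tot <- toc + tic
      over <- tot > 0 & (tot + lith) > 100
      if (any(over)) {
        scl <- (100 - lith[over]) / tot[over]
        toc[over] <- toc[over] * scl
        tic[over] <- tic[over] * scl
      }
      tic <- pmax(100 - lith - toc, 0)       # remainder closes to carbonate-free balance
    } else {
      over <- (toc + tic) > 100
      if (any(over)) {
        scl <- 100 / (toc[over] + tic[over])
        toc[over] <- toc[over] * scl; tic[over] <- tic[over] * scl
      }
    }
    out$TOC <- pmin(pmax(toc, 0), 100)
    out$TIC <- pmin(pmax(tic, 0), 100)

    # grain size: defaults with small noise, renormalized to 100
    if (is.null(out$sand)) out$sand <- pmax(10 + ar1_noise(n, 2, 0.3), 0)
    if (is.null(out$silt)) out$silt <- pmax(60 + ar1_noise(n, 2, 0.3), 0)
    if (is.null(out$clay)) out$clay <- pmax(30 + ar1_noise(n, 2, 0.3), 0)
    gs <- out$sand + out$silt + out$clay
    out$sand <- out$sand / gs * 100
    out$silt <- out$silt / gs * 100
    out$clay <- out$clay / gs * 100
    if (is.null(out$d13C_OM)) out$d13C_OM <- rep(-26, n)
    if (is.null(out$CN)) out$CN <- rep(10, n)

    rec <- as.data.frame(out)
    attr(rec, "truth") <- list(age_ce = t_ce, sed_rate = sr,
                               regimes = regimes, chron = chron)
    class(rec) <- c("proxy_record", "data.frame")
    rec
  })
}

#' Simulate diatom valve counts with a planktonic-rise signal
#'
#' Per-sample target composition is drawn from a Dirichlet distribution
#' around a mean composition whose planktonic share ramps up after
#' `change_year`; counts are multinomial with a fixed valve total.
#' Chrysophyte-cyst and microsphere counts accompany each sample.
#'
#' @param chron a `true_chronology`.
#' @param n_taxa number of diatom taxa.
#' @param planktonic_taxa integer indices of the planktonic taxa.
#' @param change_year year CE after which the planktonic share rises.
#' @param concentration Dirichlet concentration (larger = less overdispersion).
#' @param valves_per_sample valves counted per sample (>= 300 by convention).
#' @param spike microspheres added per sample (for concentration estimates).
#' @param sample_spacing sampling interval, cm.
#' @param plank_pre,plank_post planktonic share before / at the end of the rise.
#' @param mass_g dry mass analysed per sample, g.
#' @param seed RNG seed.
#' @return a `diatom_counts` data frame: depth, age_ce, taxon counts,
#'   cysts, microspheres, spike, mass_g.
#' @export
simulate_diatoms <- function(chron, n_taxa = 12, planktonic_taxa = 1:3,
                             change_year = 1950, concentration = 200,
                             valves_per_sample = 400, spike = 1e5,
                             sample_spacing = 2, plank_pre = 0.15,
                             plank_post = 0.6, mass_g = 0.1, seed = NULL) {
  if (any(planktonic_taxa < 1 | planktonic_taxa > n_taxa))
    abort("planktonic taxon index out of range", "limnoflux_parameter_error")
  if (valves_per_sample < 1 || concentration <= 0 || spike <= 0)
    abort("valves_per_sample, concentration and spike must be positive",
          "limnoflux_parameter_error")
  depths <- seq(sample_spacing / 2, max(chron$boundaries), by = sample_spacing)
  t_ce <- chron_age(chron, depths, "CE")
  n <- length(depths)
  plank <- planktonic_taxa
  benth <- setdiff(seq_len(n_taxa), plank)
  with_seed(seed, {
    # baseline composition: smoothly decaying ranks within each guild
    w_p <- exp(-0.5 * seq_along(plank)); w_p <- w_p / sum(w_p)
    w_b <- exp(-0.3 * seq_along(benth)); w_b <- w_b / sum(w_b)
    f <- pmin(pmax((t_ce - change_year) /
                     max(chron$collection_year - change_year, 1), 0), 1)
    share <- plank_pre + f * (plank_post - plank_pre)
    counts <- matrix(0L, n, n_taxa)
    for (i in seq_len(n)) {
      target <- numeric(n_taxa)
      target[plank] <- share[i] * w_p
      target[benth] <- (1 - share[i]) * w_b
      a <- stats::rgamma(n_taxa, shape = concentration * target, rate = 1)
      if (sum(a) <= 0) a <- target
      p <- a / sum(a)
      counts[i, ] <- stats::rmultinom(1, valves_per_sample, p)[, 1]
    }
    colnames(counts) <- sprintf("taxon_%02d", seq_len(n_taxa))
    cysts <- stats::rpois(n, 0.2 * valves_per_sample * (1 - 0.5 * f))
    micro <- stats::rpois(n, 120) + 1L
    out <- data.frame(depth = depths, age_ce = t_ce, counts,
                      cysts = cysts, microspheres = micro,
                      spike = spike, mass_g = mass_g)
    attr(out, "planktonic") <- colnames(counts)[plank]
    attr(out, "truth") <- list(change_year = change_year, share = share)
    class(out) <- c("diatom_counts", "data.frame")
    out
  })
}

#' Simulate a multi-lake synthetic transect
#'
#' Builds `n_lakes` cores with lake-to-lake variation in accumulation rate
#' and regime magnitude, all sharing the 1850 CE (lithogenic) and
#' 1950/1970 CE (organic) change years. Each lake carries its true
#' chronology, dated horizons, proxy record and diatom counts.
#'
#' @param n_lakes number of lakes (2-6).
#' @param seed master seed; per-lake seeds are spawned from it.
#' @param collection_year core-collection year CE (time datum).
#' @param curve calibration curve used for the radiocarbon dates
#'   (default: [synthetic_calibration_curve()]).
#' @return named list of lakes, each
#'   `list(chron, dates, proxies, diatoms, truth)`.
#' @export
simulate_transect <- function(n_lakes = 2, seed = 1, collection_year = 2015,
                              curve = synthetic_calibration_curve()) {
  stopifnot(n_lakes >= 1, n_lakes <= 6)
  lakes <- list()
  ## yr cm^-1; ~1200-yr span over 120 cm; fast enough that the flux
  ## capacity density * SR * 1e4 (~400-600 g m^-2 yr^-1) carries the
  ## configured TOC + lithogenic regimes without closure clipping
  acc_means <- c(10, 9, 11, 10, 8, 12)
  toc_steps <- rbind(c(14, 66), c(4, 12), c(3.1, 4.9),
                     c(12, 31), c(4.5, 6.5), c(10, 40))
  for (k in seq_len(n_lakes)) {
    s <- spawn_seed(seed, paste0("lake", k))
    chron <- simulate_chronology(n_sections = 24, thickness = 5,
                                 acc_mean = acc_means[k], acc_shape = 20,
                                 memory = 0.7, top_age = collection_year,
                                 collection_year = collection_year,
                                 compaction = 3, seed = s)
    span_yb <- max(chron$yb)
    ## lead-210/cesium-137 ladder through the last ~150 yr (errors growing
    ## with depth, as CRS-style chronologies do), AMS 14C below
    cand <- seq(2, 118, by = 4)
    cal_d <- cand[chron_age(chron, cand, "CE") > 1852]   # ~160-yr 210Pb range
    if (length(cal_d) > 12) cal_d <- cal_d[seq_len(12)]
    c14_d <- round(seq(max(cal_d) + 12, 118, length.out = 4))
    date_depths <- c(cal_d, c14_d)
    date_types <- rep(c("calendar", "radiocarbon"),
                      c(length(cal_d), length(c14_d)))
    errs <- c(2 + 8 * seq_along(cal_d) / length(cal_d), rep(30, length(c14_d)))
    dates <- simulate_dates(chron, date_depths, errs, date_types,
                            curve = curve, seed = s + 1L)
    # the two global anchors: lithogenic change 1850, organic change 1950
    regs <- default_regimes(toc_pre = toc_steps[k, 1],
                            toc_post = toc_steps[k, 2],
                            toc_change_year = 1950,
                            lith_pre = 100 + 15 * k,
                            lith_post = (100 + 15 * k) * 2,
                            d13c_decline = min(1 + k, 6))
    proxies <- simulate_proxies(chron, regs, sample_spacing = 2,
                                seed = s + 2L)
    diat <- simulate_diatoms(chron, seed = s + 3L)
    lakes[[sprintf("lake%02d", k)]] <-
      list(chron = chron, dates = dates, proxies = proxies, diatoms = diat,
           truth = list(span_yb = span_yb, regimes = regs,
                        cp_years = c(lith = 1850, organic = 1950)))
  }
  lakes
}
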