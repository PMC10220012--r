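## Compositional closure and flux computation per ensemble member.
##
## Fluxes follow the standard mass-accumulation-rate construction:
##   TOC_flux = density * SR * (%TOC / 100) * 1e4   [g m^-2 yr^-1]
##   L_flux   = density * SR * ((100 - %TOC - %TIC) / 100) * 1e4
## with density in g cm^-3 and SR in cm yr^-1. The 1e4 factor converts
## g cm^-2 yr^-1 to g m^-2 yr^-1 and is explicit (and tested) here.

#' Van Bemmelen factor: organic matter per unit organic carbon
#' @export
OM_FACTOR <- 1.724

#' Stoichiometric composition closure from TOC and TIC
#'
#' `%carbonates = 100.09 * TIC / 12.01` (calcite mass per mole of carbon),
#' `%organic_matter = om_factor * TOC`, and silicates close the sum to 100.
#' A negative silicate balance is clipped to 0 and flagged, with the
#' overshoot magnitude attached; it also raises a closure warning.
#'
#' @param TOC,TIC percent dry mass (>= 0), vectorized.
#' @param om_factor organic-matter conversion factor (default 1.724).
#' @return data frame: carbonates, organic_matter, silicates, clipped
#'   (logical), overshoot (percent clipped away).
#' @export
composition_closure <- function(TOC, TIC, om_factor = OM_FACTOR) {
  if (any(TOC < 0 | TIC < 0))
    abort("TOC and TIC must be >= 0", "limnoflux_parameter_error")
  carb <- 100.09 * TIC / 12.01
  om <- om_factor * TOC
  sil_raw <- 100 - carb - om
  clipped <- sil_raw < 0
  if (any(clipped))
    warning(sprintf(
      "carbonates + organic matter exceed 100%% on %d sample(s) (max overshoot %.3g%%); silicates clipped to 0",
      sum(clipped), max(-sil_raw[clipped])), call. = FALSE)
  data.frame(carbonates = carb, organic_matter = om,
             silicates = pmax(sil_raw, 0), clipped = clipped,
             overshoot = pmax(-sil_raw, 0))
}

#' Compute TOC and lithogenic fluxes per age-model ensemble member
#'
#' The sedimentation rate attached to a sample is the interval rate between
#' the midpoints towards its neighbouring samples (centred), which is
#' stable for unevenly spaced samples. Samples flagged as event layers are
#' excluded when `exclude_events = TRUE`.
#'
#' @param rec a proxy record: data frame with `depth`, `TOC`, `TIC` and
#'   (unless `density_fallback` is given) `density`; optional logical
#'   `event` column.
#' @param ens an `age_depth_ensemble` covering the sample depths.
#' @param density_fallback constant dry bulk density, g cm^-3, used where
#'   the record has none.
#' @param exclude_events drop event-flagged samples.
#' @return a `flux_ensemble`: sample depths, member x sample matrices of
#'   mid-ages (yr CE), TOC_flux and L_flux (g m^-2 yr^-1).
#' @export
compute_fluxes <- function(rec, ens, density_fallback = NULL,
                           exclude_events = TRUE) {
  need <- c("depth", "TOC", "TIC")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    abort(paste("proxy record lacks column(s):", paste(miss, collapse = ", ")),
          "limnoflux_schema_error")
  if (exclude_events && "event" %in% names(rec))
    rec <- rec[!isTRUE_vec(rec$event), , drop = FALSE]
  o <- order(rec$depth)
  rec <- rec[o, , drop = FALSE]
  dens <- if ("density" %in% names(rec)) rec$density else rep(NA_real_, nrow(rec))
  if (anyNA(dens)) {
    if (is.null(density_fallback))
      abort(sprintf("missing density at depth(s) %s and no fallback configured",
                    paste(signif(rec$depth[is.na(dens)], 4), collapse = ", ")),
            "limnoflux_data_error")
    dens[is.na(dens)] <- density_fallback
  }
  d <- rec$depth
  n <- length(d)
  if (n < 1L) abort("no samples to compute fluxes for", "limnoflux_data_error")
  ## centred interval boundaries: sample midpoints, clamped to end samples
  b <- if (n == 1L) c(d, d + 1e-6) else c(d[1], (d[-1] + d[-n]) / 2, d[n])
  b <- pmax(pmin(b, max(ens$depth)), min(ens$depth))
  sr <- sed_rate_ensemble(ens, b)                  # members x n intervals
  age_ce <- ensemble_ages_at(ens, pmin(pmax(d, min(ens$depth)), max(ens$depth)), "CE")
  toc_f <- sweep(sr, 2, dens * rec$TOC / 100 * 1e4, `*`)
  l_f <- sweep(sr, 2, dens * (100 - rec$TOC - rec$TIC) / 100 * 1e4, `*`)
  structure(list(depth = d, age_ce = age_ce, toc_flux = toc_f, l_flux = l_f,
                 n_members = nrow(sr), collection_year = ens$collection_year),
            class = "flux_ensemble")
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Sediment-trap fluxes
#'
#' Utility for comparing core-top fluxes with trap deployments:
#' `total = dry_mass / (trap_area * deployment)`; the TOC and lithogenic
#' shares apply the same percentages as the core fluxes.
#'
#' @param dry_mass collected dry mass, g.
#' @param trap_area trap collecting area, m^2.
#' @param deployment deployment length, yr.
#' @param TOC,TIC percent dry mass of the trap material.
#' @return list: total, toc_flux, lithogenic_flux (g m^-2 yr^-1).
#' @export
trap_flux <- function(dry_mass, trap_area, deployment, TOC, TIC = 0) {
  if (any(c(dry_mass, trap_area, deployment) <= 0))
    abort("dry_mass, trap_area and deployment must be > 0",
          "limnoflux_parameter_error")
  total <- dry_mass / (trap_area * deployment)
  list(total = total, toc_flux = total * TOC / 100,
       lithogenic_flux = total * (100 - TOC - TIC) / 100)
}

#' Core-top flux (mean over the first centimetre)
#'
#' @param fe a `flux_ensemble`.
#' @param depth_max samples at or above this depth enter the mean, cm.
#' @return list with the ensemble-median core-top TOC and lithogenic flux.
#' @export
core_top_flux <- function(fe, depth_max = 1) {
  sel <- fe$depth <= depth_max
  if (!any(sel)) abort("no samples within the core-top window",
                       "limnoflux_data_error")
  list(toc_flux = stats::median(rowMeans(fe$toc_flux[, sel, drop = FALSE])),
       l_flux = stats::median(rowMeans(fe$l_flux[, sel, drop = FALSE])))
}

#' Bin a flux ensemble onto a regular time grid
#'
#' Per member and per bin, the mean of the samples whose member-specific
#' mid-age falls in the bin; NA where a member leaves a bin empty.
#'
#' @param fe a `flux_ensemble`.
#' @param bin_width bin width, yr.
#' @param t0,t1 window, yr CE (`t0 < t1`).
#' @param what `"toc_flux"` or `"l_flux"`.
#' @return list: bin_centre, values (member x bin matrix), occupancy
#'   (samples per bin per member).
#' @export
bin_flux_ensemble <- function(fe, bin_width, t0, t1,
                              what = c("toc_flux", "l_flux")) {
  what <- match.arg(what)
  if (bin_width <= 0 || t0 >= t1)
    abort("need bin_width > 0 and t0 < t1", "limnoflux_parameter_error")
  breaks <- seq(t0, t1, by = bin_width)
  if (utils::tail(breaks, 1) < t1) breaks <- c(breaks, utils::tail(breaks, 1) + bin_width)
  v <- fe[[what]]
  M <- nrow(v)
  nb <- length(breaks) - 1L
  vals <- matrix(NA_real_, M, nb)
  occ <- matrix(0L, M, nb)
  any_in <- FALSE
  for (m in seq_len(M)) {
    t_m <- fe$age_ce[m, ]
    idx <- findInterval(t_m, breaks, rightmost.closed = TRUE)
    ok <- idx >= 1L & idx <= nb
    if (any(ok)) {
      any_in <- TRUE
      sm <- tapply(v[m, ok], idx[ok], mean)
      cn <- tapply(v[m, ok], idx[ok], length)
      vals[m, as.integer(names(sm))] <- as.numeric(sm)
      occ[m, as.integer(names(cn))] <- as.integer(cn)
    }
  }
  if (!any_in)
    abort("no samples fall inside the requested time window", "limnoflux_data_error")
  list(bin_centre = (breaks[-1] + breaks[-length(breaks)]) / 2,
       values = vals, occupancy = occ)
}

#' Flux band summary (median and central quantile bands per bin)
#'
#' @param binned result of [bin_flux_ensemble()].
#' @return data frame: bin_centre, median, q25, q75, q2.5, q97.5.
#' @export
flux_band_summary <- function(binned) {
  qf <- function(p) apply(binned$values, 2, function(x)
    if (all(is.na(x))) NA_real_ else stats::quantile(x, p, na.rm = TRUE))
  data.frame(bin_centre = binned$bin_centre,
             median = qf(0.5), q25 = qf(0.25), q75 = qf(0.75),
             q2.5 = qf(0.025), q97.5 = qf(0.975))
}

#' Ensemble-median flux series at the sample resolution
#'
#' Collapses a `flux_ensemble` to one time series (median age and median
#' flux per sample across members), the default input for change-point
#' detection.
#'
#' @param fe a `flux_ensemble`.
#' @param what `"toc_flux"` or `"l_flux"`.
#' @return data frame: time (yr CE, increasing), value.
#' @export
median_flux_series <- function(fe, what = c("toc_flux", "l_flux")) {
  what <- match.arg(what)
  t_med <- apply(fe$age_ce, 2, stats::median)
  v_med <- apply(fe[[what]], 2, stats::median)
  o <- order(t_med)
  data.frame(time = t_med[o], value = v_med[o])
}
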