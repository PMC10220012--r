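## End-to-end pipeline: chronologies -> fluxes -> change points -> PCAs.

#' Run the full reconstruction pipeline
#'
#' Deterministic given (config, seed): per-stage seeds are spawned from the
#' master seed, so two runs with the same config produce byte-identical
#' summary tables. A failure in one lake is quarantined (recorded in the
#' run summary); the run fails only when every lake fails.
#'
#' @param config a validated config list ([read_config()] /
#'   [pipeline_config()]).
#' @return invisibly, a result bundle: per-lake chronologies, flux
#'   ensembles, change-point reports, PCA summaries, and the run summary
#'   (also written to `out_dir`).
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  t_start <- Sys.time()
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- config_hash(cfg)
  seed <- as.integer(cfg$seed)
  curve <- if (!is.null(cfg$curve)) read_calibration_curve(cfg$curve) else NULL
  prov <- function(stage) list(generator = "limnoflux",
                               config_hash = cfg_hash, seed = seed,
                               stage = stage)
  log <- list()
  note <- function(stage, msg) {
    log[[length(log) + 1L]] <<- sprintf("[%s] %s: %s",
                                        format(Sys.time(), "%H:%M:%S"), stage, msg)
  }

  lakes_out <- list()
  errors <- list()
  cp_rows <- list()
  for (nm in names(cfg$lakes)) {
    res <- tryCatch({
      t0 <- Sys.time()
      lk <- cfg$lakes[[nm]]
      dates <- read_date_table(lk$dates)
      proxies <- read_proxy_table(lk$proxies,
                                  density_fallback = cfg$flux$density_fallback)
      am_args <- cfg$age_model
      am_args$acc_mean <- am_args$acc_mean   # NULL = auto
      settings <- do.call(age_model_settings, am_args[names(am_args) %in%
        names(formals(age_model_settings))])
      ens <- fit_age_model(dates, curve, settings,
                           seed = spawn_seed(seed, paste0("agemodel-", nm)),
                           core_depth = max(proxies$depth))
      note(nm, sprintf("age model: %d members, Rhat %.3f",
                       nrow(ens$ages),
                       ifelse(is.null(ens$diagnostics$rhat), NA,
                              ens$diagnostics$rhat)))
      fe <- compute_fluxes(proxies, ens,
                           density_fallback = cfg$flux$density_fallback)
      ## change points on the four canonical series
      series <- list(
        TOC_flux = median_flux_series(fe, "toc_flux"),
        L_flux = median_flux_series(fe, "l_flux"))
      med_age <- apply(fe$age_ce, 2, stats::median)
      for (v in c("d13C_OM", "CN")) {
        if (v %in% names(proxies)) {
          o <- order(med_age)
          series[[v]] <- data.frame(time = med_age[o], value = proxies[[v]][o])
        }
      }
      for (v in names(series)) {
        cp <- detect_changepoints(series[[v]],
                                  seed = spawn_seed(seed, paste0("cp-", nm, v)))
        if (nrow(cp$cumsum))
          cp_rows[[length(cp_rows) + 1L]] <- data.frame(
            variable = v, lake = nm, method = "cumsum",
            cp_time = cp$cumsum$cp_time, sign = cp$cumsum$sign_change,
            statistic = cp$cumsum$slope_after - cp$cumsum$slope_before,
            interval_start = NA_real_, interval_end = NA_real_)
        if (nrow(cp$gam))
          cp_rows[[length(cp_rows) + 1L]] <- data.frame(
            variable = v, lake = nm, method = "gam",
            cp_time = cp$gam$cp_time, sign = cp$gam$sign,
            statistic = NA_real_,
            interval_start = cp$gam$interval_start,
            interval_end = cp$gam$interval_end)
      }
      ## per-lake compositional PCA (TOC, TIC, %sand + any element columns)
      comp_vars <- intersect(c("TOC", "TIC", "sand",
                               "Al", "Ca", "Fe", "K", "Mg", "Mn", "Na",
                               "P", "S", "Si", "Sr", "Ti"), names(proxies))
      pca_comp <- if (length(comp_vars) >= 2)
        standardized_pca(as.matrix(proxies[, comp_vars])) else NULL
      ## outputs
      write_table_prov(ensemble_summary(ens, units = "CE"),
                       file.path(cfg$out_dir, paste0(nm, "_chronology.csv")),
                       prov(paste0("agemodel-", nm)))
      bw <- cfg$pca$bin_width
      for (w in c("toc_flux", "l_flux")) {
        b <- bin_flux_ensemble(fe, bw, cfg$pca$t0, cfg$pca$t1, w)
        write_table_prov(flux_band_summary(b),
                         file.path(cfg$out_dir, sprintf("%s_%s_bands.csv", nm, w)),
                         prov(paste0("flux-", nm)))
      }
      note(nm, sprintf("done in %.1f s",
                       as.numeric(difftime(Sys.time(), t0, units = "secs"))))
      list(ens = ens, fluxes = fe, proxies = proxies, pca_comp = pca_comp,
           med_age = med_age)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[nm]] <- conditionMessage(res)
      note(nm, paste("FAILED:", conditionMessage(res)))
    } else lakes_out[[nm]] <- res
  }
  if (!length(lakes_out))
    abort(paste("all lakes failed:",
                paste(sprintf("%s (%s)", names(errors), unlist(errors)),
                      collapse = "; ")), "limnoflux_pipeline_error")

  cp_report <- if (length(cp_rows)) do.call(rbind, cp_rows)
  else data.frame(variable = character(), lake = character(),
                  method = character(), cp_time = numeric(), sign = numeric(),
                  statistic = numeric(), interval_start = numeric(),
                  interval_end = numeric())
  write_table_prov(cp_report, file.path(cfg$out_dir, "changepoints.csv"),
                   prov("changepoints"))

  ## cross-lake age-uncertain PCAs: organic and lithogenic variable sets
  org <- list(); lit <- list()
  for (nm in names(lakes_out)) {
    L <- lakes_out[[nm]]
    org[[length(org) + 1L]] <- au_from_flux(L$fluxes, "toc_flux",
                                            paste0(nm, ".TOC_flux"))
    if ("CN" %in% names(L$proxies))
      org[[length(org) + 1L]] <- au_series(paste0(nm, ".CN"),
                                           L$fluxes$age_ce, L$proxies$CN)
    if ("d13C_OM" %in% names(L$proxies))
      org[[length(org) + 1L]] <- au_series(paste0(nm, ".d13C_OM"),
                                           L$fluxes$age_ce, L$proxies$d13C_OM)
    lit[[length(lit) + 1L]] <- au_from_flux(L$fluxes, "l_flux",
                                            paste0(nm, ".L_flux"))
    if (!is.null(L$pca_comp))
      lit[[length(lit) + 1L]] <- au_series(paste0(nm, ".PC1_comp"),
                                           L$fluxes$age_ce,
                                           L$pca_comp$scores[, 1])
  }
  pca_au <- list()
  for (set in c("organic", "lithogenic")) {
    sl <- if (set == "organic") org else lit
    pca_au[[set]] <- tryCatch(
      age_uncertain_pca(sl, bin_width = cfg$pca$bin_width, t0 = cfg$pca$t0,
                        t1 = cfg$pca$t1,
                        n_members_used = cfg$pca$n_members_used,
                        seed = spawn_seed(seed, paste0("pca-", set))),
      error = function(e) { note("pca", paste(set, "FAILED:",
                                              conditionMessage(e))); NULL })
    if (!is.null(pca_au[[set]]))
      write_table_prov(pca_au[[set]]$summary,
                       file.path(cfg$out_dir, sprintf("pca_au_%s.csv", set)),
                       prov(paste0("pca-", set)))
  }

  summary <- list(config_hash = cfg_hash, seed = seed,
                  lakes_ok = names(lakes_out), lakes_failed = errors,
                  elapsed_s = as.numeric(difftime(Sys.time(), t_start,
                                                  units = "secs")),
                  log = unlist(log))
  jsonlite::write_json(summary, file.path(cfg$out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(lakes = lakes_out, changepoints = cp_report,
                 pca_au = pca_au, summary = summary))
}

## Stable hash of the configuration (file content independent).
config_hash <- function(cfg) {
  cfg$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
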