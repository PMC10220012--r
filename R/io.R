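## Delimited-table readers/writers and configuration.
##
## Dialect: comma-separated, UTF-8, "." decimal, ISO header names, lines
## starting with '#' are provenance/comment lines. No locale inference.

#' Read a dated-horizons table
#'
#' Expected columns: `labID, age, error, depth, type`; optional `excluded`.
#'
#' @param path CSV file.
#' @return a `date_table`.
#' @export
read_date_table <- function(path) {
  d <- read_csv_checked(path, c("labID", "age", "error", "depth", "type"))
  date_table(d$labID, d$age, d$error, d$depth, d$type,
             if ("excluded" %in% names(d)) d$excluded else FALSE)
}

#' Read a calibration curve (3-column: cal BP, 14C age, error)
#' @param path delimited file; '#' lines and an optional header are skipped.
#' @export
read_calibration_curve <- function(path) {
  first <- readLines(path, n = 50L)
  first <- first[!startsWith(trimws(first), "#") & nzchar(trimws(first))][1]
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, ",")[[1]][1])))
  d <- utils::read.csv(path, header = has_header, comment.char = "#",
                       strip.white = TRUE)
  if (ncol(d) < 3L)
    abort("calibration curve needs 3 columns: cal BP, 14C age, error",
          "limnoflux_schema_error")
  calibration_curve(d[[1]], d[[2]], d[[3]])
}

#' Read a proxy table
#'
#' One row per depth; required columns `depth`, `TOC`, `TIC`; all other
#' columns are preserved. Returns a validation report in
#' `attr(, "validation")` flagging rows with TOC+TIC > 100, negative
#' carbon, non-positive density, or grain sizes not summing to 100 +- 0.5.
#'
#' @param path CSV file.
#' @param density_fallback constant density used when the file has no
#'   `density` column; an error without it.
#' @export
read_proxy_table <- function(path, density_fallback = NULL) {
  d <- read_csv_checked(path, c("depth", "TOC", "TIC"))
  if (!"density" %in% names(d) && is.null(density_fallback))
    abort(sprintf("file '%s' lacks a 'density' column and no fallback is configured",
                  basename(path)), "limnoflux_schema_error")
  issues <- list()
  flag <- function(rows, what) {
    if (length(rows)) issues[[length(issues) + 1L]] <<-
      data.frame(row = rows, issue = what)
  }
  flag(which(d$TOC + d$TIC > 100), "TOC+TIC > 100")
  flag(which(d$TOC < 0 | d$TIC < 0), "negative carbon fraction")
  if ("density" %in% names(d)) flag(which(d$density <= 0), "non-positive density")
  if (all(c("sand", "silt", "clay") %in% names(d)))
    flag(which(abs(d$sand + d$silt + d$clay - 100) > 0.5),
         "grain-size fractions do not sum to 100 +- 0.5")
  rep <- if (length(issues)) do.call(rbind, issues)
  else data.frame(row = integer(), issue = character())
  attr(d, "validation") <- rep
  class(d) <- c("proxy_record", "data.frame")
  d
}

#' Read a diatom count table
#'
#' Samples as rows, taxa as columns; reserved columns `depth`, `cysts`,
#' `microspheres`, `spike`, `mass_g` (and optional `age_ce`).
#' @param path CSV file.
#' @export
read_count_table <- function(path) {
  d <- read_csv_checked(path, "depth")
  taxa <- setdiff(names(d), c("depth", "age_ce", "cysts", "microspheres",
                              "spike", "mass_g"))
  if (!length(taxa))
    abort("count table has no taxon columns", "limnoflux_schema_error")
  m <- as.matrix(d[, taxa])
  if (any(m < 0) || any(m != round(m)))
    abort("taxon counts must be non-negative integers", "limnoflux_data_error")
  class(d) <- c("diatom_counts", "data.frame")
  d
}

## CSV reader with schema checks and row-indexed numeric validation.
read_csv_checked <- function(path, required) {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), "limnoflux_io_error")
  d <- utils::read.csv(path, comment.char = "#", strip.white = TRUE,
                       stringsAsFactors = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss))
    abort(sprintf("file '%s' lacks required column(s): %s",
                  basename(path), paste(miss, collapse = ", ")),
          "limnoflux_schema_error")
  num_cols <- setdiff(names(d), c("labID", "type"))
  for (cn in num_cols) {
    if (is.character(d[[cn]])) {
      v <- suppressWarnings(as.numeric(d[[cn]]))
      bad <- which(is.na(v) & nzchar(trimws(d[[cn]])))
      if (length(bad))
        abort(sprintf("file '%s', column '%s': non-numeric value at row(s) %s",
                      basename(path), cn, paste(bad, collapse = ", ")),
              "limnoflux_parse_error")
      d[[cn]] <- v
    }
  }
  d
}

#' Write a table with a provenance header
#'
#' @param x data frame.
#' @param path output CSV.
#' @param provenance named list written as `# key: value` lines.
#' @export
write_table_prov <- function(x, path, provenance = list()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(provenance),
                     vapply(provenance, function(v) paste(format(v), collapse = " "),
                            character(1))), con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration (JSON)
#'
#' @param path JSON file; see [pipeline_config()] for the expected fields.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    abort(sprintf("config file not found: %s", path), "limnoflux_io_error")
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  validate_config(cfg)
}

#' Assemble a pipeline configuration in code
#'
#' @param lakes named list; each element a list with `dates`, `proxies`
#'   and optionally `counts` file paths.
#' @param curve calibration-curve file path.
#' @param out_dir output directory.
#' @param seed master seed.
#' @param age_model,flux,changepoint,pca per-stage option lists (merged
#'   over the package defaults).
#' @export
pipeline_config <- function(lakes, curve, out_dir, seed = 1,
                            age_model = list(), flux = list(),
                            changepoint = list(), pca = list()) {
  validate_config(list(lakes = lakes, curve = curve, out_dir = out_dir,
                       seed = seed, age_model = age_model, flux = flux,
                       changepoint = changepoint, pca = pca))
}

validate_config <- function(cfg) {
  for (f in c("lakes", "out_dir", "seed")) {
    if (is.null(cfg[[f]]))
      abort(sprintf("config lacks field '%s'", f), "limnoflux_config_error")
  }
  if (!length(cfg$lakes)) abort("config has no lakes", "limnoflux_config_error")
  for (nm in names(cfg$lakes)) {
    lk <- cfg$lakes[[nm]]
    for (f in c("dates", "proxies")) {
      if (is.null(lk[[f]]))
        abort(sprintf("lake '%s' lacks '%s' path", nm, f), "limnoflux_config_error")
      if (!file.exists(lk[[f]]))
        abort(sprintf("lake '%s': file not found: %s", nm, lk[[f]]),
              "limnoflux_config_error")
    }
    if (!is.null(lk$counts) && !file.exists(lk$counts))
      abort(sprintf("lake '%s': file not found: %s", nm, lk$counts),
            "limnoflux_config_error")
  }
  if (!is.null(cfg$curve) && !file.exists(cfg$curve))
    abort(sprintf("calibration curve not found: %s", cfg$curve),
          "limnoflux_config_error")
  defaults <- list(age_model = list(), flux = list(om_factor = OM_FACTOR),
                   changepoint = list(), pca = list(bin_width = 25, t0 = 800,
                                                    t1 = 2015,
                                                    n_members_used = 100))
  for (nm in names(defaults))
    cfg[[nm]] <- utils::modifyList(defaults[[nm]], as.list(cfg[[nm]]))
  cfg
}

#' Write the bundled synthetic transect to disk as a fixture
#'
#' Emits, per lake, the delimited tables the pipeline consumes (dates,
#' proxies, diatom counts), a calibration curve, a pipeline config, and a
#' ground-truth sidecar (JSON) with true ages, regime parameters and
#' change-point years.
#'
#' @param dir output directory (created).
#' @param n_lakes number of lakes.
#' @param seed master seed.
#' @return the path of the written config file.
#' @export
write_transect_fixture <- function(dir, n_lakes = 2, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  curve <- synthetic_calibration_curve()
  lakes <- simulate_transect(n_lakes, seed = seed)
  curve_path <- file.path(dir, "calibration_curve.csv")
  utils::write.csv(as.data.frame(curve), curve_path, row.names = FALSE)
  cfg_lakes <- list()
  for (nm in names(lakes)) {
    lk <- lakes[[nm]]
    dp <- file.path(dir, paste0(nm, "_dates.csv"))
    pp <- file.path(dir, paste0(nm, "_proxies.csv"))
    cp <- file.path(dir, paste0(nm, "_counts.csv"))
    utils::write.csv(as.data.frame(lk$dates), dp, row.names = FALSE)
    utils::write.csv(as.data.frame(lk$proxies), pp, row.names = FALSE)
    utils::write.csv(as.data.frame(lk$diatoms), cp, row.names = FALSE)
    truth <- list(
      true_age_ce = as.numeric(chron_age(lk$chron, lk$proxies$depth, "CE")),
      depth = as.numeric(lk$proxies$depth),
      cp_years = as.list(lk$truth$cp_years),
      regimes = lapply(lk$truth$regimes, unclass),
      acc = as.numeric(lk$chron$acc),
      boundaries = as.numeric(lk$chron$boundaries))
    jsonlite::write_json(truth, file.path(dir, paste0(nm, "_truth.json")),
                         auto_unbox = TRUE, digits = NA)
    cfg_lakes[[nm]] <- list(dates = dp, proxies = pp, counts = cp)
  }
  cfg <- list(lakes = cfg_lakes, curve = curve_path,
              out_dir = file.path(dir, "out"), seed = seed,
              age_model = list(n_iter = 4000, burn_in = 1000,
                               n_members = 300),
              pca = list(n_members_used = 50))
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
  cfg_path
}
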