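## Dated-horizon tables and radiocarbon calibration.

#' Construct a table of dated horizons
#'
#' The likelihood data for the age-depth model. Radiocarbon ages are
#' conventional 14C yr BP; calendar-type dates (lead-210-derived,
#' cesium-137, known events) are calendar years CE.
#'
#' @param labID sample labels.
#' @param age measured age (14C yr BP or calendar yr CE, by `type`).
#' @param error 1-sigma error, yr (> 0).
#' @param depth depth, cm (>= 0).
#' @param type `"radiocarbon"` or `"calendar"`.
#' @param excluded logical; excluded dates are kept but not used in fitting.
#' @export
date_table <- function(labID, age, error, depth, type = "calendar",
                       excluded = FALSE) {
  d <- data.frame(labID = as.character(labID), age = as.numeric(age),
                  error = as.numeric(error), depth = as.numeric(depth),
                  type = as.character(type),
                  excluded = rep_len(as.logical(excluded), length(age)))
  validate_date_table(d)
  class(d) <- c("date_table", "data.frame")
  d
}

validate_date_table <- function(d) {
  if (nrow(d) < 1L) abort("at least one date is required", "limnoflux_data_error")
  if (any(d$error <= 0)) abort("date errors must be > 0", "limnoflux_data_error")
  if (any(d$depth < 0)) abort("date depths must be >= 0", "limnoflux_data_error")
  if (!all(d$type %in% c("radiocarbon", "calendar")))
    abort("date type must be 'radiocarbon' or 'calendar'", "limnoflux_schema_error")
  invisible(d)
}

#' Construct a radiocarbon calibration curve
#'
#' @param cal_bp calendar-age grid, yr BP (strictly increasing).
#' @param c14_age conventional 14C age at each grid point.
#' @param error curve 1-sigma error (> 0).
#' @export
calibration_curve <- function(cal_bp, c14_age, error) {
  o <- order(cal_bp)
  cal_bp <- cal_bp[o]; c14_age <- c14_age[o]; error <- rep_len(error, length(cal_bp))[o]
  if (any(diff(cal_bp) <= 0))
    abort("calibration-curve calendar grid must be strictly increasing",
          "limnoflux_schema_error")
  if (any(error <= 0))
    abort("calibration-curve errors must be > 0", "limnoflux_schema_error")
  structure(data.frame(cal_bp = cal_bp, c14_age = c14_age, error = error),
            class = c("calibration_curve", "data.frame"))
}

#' Identity calibration curve (14C age == calendar age)
#'
#' Useful for tests and noiseless limits.
#' @param span calendar range, yr BP.
#' @param error constant curve error, yr.
#' @export
identity_calibration_curve <- function(span = c(-70, 10000), error = 1e-6) {
  grid <- seq(span[1], span[2], by = 10)
  calibration_curve(grid, grid, error)
}

#' Synthetic calibration curve with decadal wiggles
#'
#' A stand-in for a published calibration-curve distribution: monotone on
#' average (slope 1) with sinusoidal wiggles and an error growing with age.
#' It is synthetic: do not use for real chronologies.
#'
#' @param span calendar range, yr BP.
#' @export
synthetic_calibration_curve <- function(span = c(-70, 10000)) {
  grid <- seq(span[1], span[2], by = 5)
  c14 <- grid + 25 * sin(grid / 80) + 10 * sin(grid / 17)
  err <- 8 + grid * 2e-3
  calibration_curve(grid, c14, pmax(err, 5))
}

#' Calibrate a radiocarbon date onto the calendar-age grid
#'
#' Posterior density over calendar age proportional to a Gaussian kernel of
#' `(age - mu(theta))` with scale `sqrt(error^2 + sigma_curve(theta)^2)`,
#' normalized to integrate to 1 by the trapezoid rule on the curve grid.
#'
#' @param age conventional 14C age, yr BP.
#' @param error 1-sigma measurement error, yr.
#' @param curve a `calibration_curve`.
#' @return data frame `cal_bp`, `density`.
#' @export
calibrate_date <- function(age, error, curve) {
  lo <- min(curve$c14_age) - 5 * error
  hi <- max(curve$c14_age) + 5 * error
  if (age < lo || age > hi)
    abort(sprintf(
      "14C age %.1f outside the curve span [%.1f, %.1f] (+-5 sigma)",
      age, min(curve$c14_age), max(curve$c14_age)), "limnoflux_calibration_error")
  sc <- sqrt(error^2 + curve$error^2)
  dens <- stats::dnorm(age, mean = curve$c14_age, sd = sc)
  z <- trapz(curve$cal_bp, dens)
  if (z <= 0)
    abort("calibration produced zero mass on the grid", "limnoflux_calibration_error")
  data.frame(cal_bp = curve$cal_bp, density = dens / z)
}

## Trapezoid-rule integral on an ordered grid.
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
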