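## Regime-shift detection on unevenly spaced proxy time series.
##
## Two complementary procedures:
##  * CumSum: cumulative sum of deviations from the series mean. A slope
##    sign change of the CumSum curve marks a phase boundary; candidates
##    are weighed by the slope change and the number of supporting points.
##  * GAM: a penalized cubic regression spline trend; periods where the
##    simultaneous confidence band on the first derivative excludes zero
##    are significant change intervals.

#' Cumulative sum of deviations from the mean
#'
#' `C_k = sum_{i<=k} (x_i - mean(x))`; the terminal value is zero by
#' construction (an algebraic identity used as a self-check downstream).
#'
#' @param x numeric series (>= 2 points, no NAs).
#' @return numeric vector of the same length.
#' @export
cumsum_curve <- function(x) {
  if (length(x) < 2L || anyNA(x))
    abort("cumsum_curve needs >= 2 non-missing points", "limnoflux_data_error")
  cumsum(x - mean(x))
}

#' Change points from CumSum slope-sign changes
#'
#' Change points are slope-sign flips of the CumSum curve. Candidates are
#' located recursively: within a segment the candidate is the point of
#' maximal deviation of the curve from the segment's chord (for the whole
#' series this is the curve's principal extremum); it is accepted when
#' both flanks hold at least `min_segment` points, the least-squares
#' slopes of the two flanks have opposite signs, and the slope change
#' exceeds `slope_delta_min * range(curve) / span(time)`. Accepted
#' candidates split the segment and both halves are searched in turn, so
#' noise-scale wiggles of the curve never anchor a flank.
#'
#' @param x series values (the raw variable, not the CumSum).
#' @param times observation times, yr CE, strictly increasing.
#' @param min_segment minimum points per flank (>= 3).
#' @param slope_delta_min significance threshold as a fraction of the
#'   curve-range-per-time-span scale.
#' @return a `changepoint_result` data frame: cp_time (midpoint between
#'   the flanking samples), sign_change (+1 negative-to-positive slope,
#'   -1 the reverse), slope_before, slope_after, n_before, n_after.
#' @export
cumsum_changepoints <- function(x, times, min_segment = 5,
                                slope_delta_min = 0.1) {
  if (min_segment < 3) abort("min_segment must be >= 3", "limnoflux_parameter_error")
  n <- length(x)
  if (n < 2 * min_segment)
    abort(sprintf("series too short: %d points < 2 * min_segment", n),
          "limnoflux_insufficient_data_error")
  if (length(times) != n || any(diff(times) <= 0))
    abort("times must be strictly increasing and match the series",
          "limnoflux_data_error")
  C <- cumsum_curve(x)
  rng <- diff(range(C))
  if (rng == 0) return(empty_cp_result("cumsum"))
  thr <- slope_delta_min * rng / diff(range(times))

  out <- list()
  segment <- function(i0, i1) {
    if (i1 - i0 + 1L < 2L * min_segment) return(invisible())
    ## candidate: maximal deviation from the chord through the segment ends
    idx <- (i0 + min_segment - 1L):(i1 - min_segment + 1L)
    chord <- C[i0] + (C[i1] - C[i0]) * (times[idx] - times[i0]) /
      (times[i1] - times[i0])
    k <- idx[which.max(abs(C[idx] - chord))]
    iL <- i0:k; iR <- k:i1
    bL <- ls_slope(times[iL], C[iL])
    bR <- ls_slope(times[iR], C[iR])
    if (!is.finite(bL) || !is.finite(bR)) return(invisible())
    if (sign(bL) == sign(bR) || abs(bR - bL) <= thr) return(invisible())
    out[[length(out) + 1L]] <<- data.frame(
      method = "cumsum",
      cp_time = (times[k] + times[min(k + 1L, n)]) / 2,
      sign_change = if (bR > bL) 1 else -1,
      slope_before = bL, slope_after = bR,
      n_before = length(iL), n_after = length(iR),
      stringsAsFactors = FALSE)
    segment(i0, k)
    segment(k, i1)
  }
  segment(1L, n)
  if (!length(out)) return(empty_cp_result("cumsum"))
  res <- do.call(rbind, out)
  res <- res[order(res$cp_time), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("changepoint_result", "data.frame")
  res
}

ls_slope <- function(t, y) {
  if (length(t) < 2L) return(NA_real_)
  tc <- t - mean(t)
  sum(tc * (y - mean(y))) / sum(tc^2)
}

empty_cp_result <- function(method) {
  res <- data.frame(method = character(), cp_time = numeric(),
                    sign_change = numeric(), slope_before = numeric(),
                    slope_after = numeric(), n_before = integer(),
                    n_after = integer(), stringsAsFactors = FALSE)
  class(res) <- c("changepoint_result", "data.frame")
  res
}

#' Fit a penalized-spline (GAM) trend to a time series
#'
#' Cubic regression spline on time with the smoothing parameter chosen by
#' generalized cross-validation (default) or restricted likelihood.
#' Returns the fit together with the Bayesian coefficient covariance used
#' for simultaneous inference on derivatives.
#'
#' @param times observation times, yr CE, strictly increasing (no ties).
#' @param values observed values.
#' @param basis_dim spline basis dimension (reduced to `floor(n/2)` with a
#'   notice when `n <= basis_dim`). The default `NULL` picks
#'   `max(10, min(30, floor(n/2)))`: a basis generous enough that decadal
#'   changes in multi-century series are representable, with the penalty
#'   (not the basis ceiling) controlling smoothness.
#' @param method `"GCV.Cp"` or `"REML"`.
#' @return a `gam_trend`: the mgcv fit, fitted values, effective degrees
#'   of freedom, and the inputs.
#' @export
fit_gam_trend <- function(times, values, basis_dim = NULL,
                          method = c("GCV.Cp", "REML")) {
  method <- match.arg(method)
  n <- length(values)
  if (is.null(basis_dim)) basis_dim <- max(10, min(30, floor(n / 2)))
  if (n < 10) abort("GAM trend needs >= 10 points", "limnoflux_insufficient_data_error")
  if (length(times) != n || anyNA(times) || anyNA(values))
    abort("times/values must be complete and of equal length", "limnoflux_data_error")
  if (anyDuplicated(times))
    abort("duplicate time values", "limnoflux_data_error")
  if (n <= basis_dim) {
    basis_dim <- max(floor(n / 2), 4)
    message(sprintf("basis_dim reduced to %d (n = %d)", basis_dim, n))
  }
  dat <- data.frame(t = as.numeric(times), y = as.numeric(values))
  fit <- mgcv::gam(y ~ s(t, k = basis_dim, bs = "cr"), data = dat,
                   method = method)
  structure(list(fit = fit, times = dat$t, values = dat$y,
                 fitted = as.numeric(stats::fitted(fit)),
                 edf = sum(fit$edf), basis_dim = basis_dim,
                 method = method),
            class = "gam_trend")
}

#' Significant-change intervals from the GAM first derivative
#'
#' The first derivative of the fitted trend is evaluated by central finite
#' differences of the spline basis on a 2001-point grid (step =
#' time-range/2000). A simultaneous confidence band is built from the
#' max-|t| statistic over draws from the Bayesian coefficient covariance;
#' contiguous grid runs where the band excludes zero are merged into
#' intervals (runs shorter than 2 grid steps are discarded as numerical
#' noise).
#'
#' @param trend a `gam_trend`.
#' @param n_draws coefficient draws for the max-statistic (>= 1000).
#' @param level simultaneous coverage level.
#' @param seed RNG seed for the draws.
#' @return a `changepoint_result` data frame: interval_start, interval_end
#'   (yr CE), sign of the derivative within, and cp_time (interval centre).
#' @export
derivative_changepoints <- function(trend, n_draws = 2000, level = 0.95,
                                    seed = NULL) {
  if (n_draws < 1000) abort("n_draws must be >= 1000", "limnoflux_parameter_error")
  fit <- trend$fit
  tr <- range(trend$times)
  grid <- seq(tr[1], tr[2], length.out = 2001L)
  h <- diff(tr) / 2000
  Xf <- stats::predict(fit, newdata = data.frame(t = pmin(grid + h / 2, tr[2])),
                       type = "lpmatrix")
  Xb <- stats::predict(fit, newdata = data.frame(t = pmax(grid - h / 2, tr[1])),
                       type = "lpmatrix")
  Xd <- (Xf - Xb) / h
  beta <- stats::coef(fit)
  V <- fit$Vp
  ev <- eigen(V, symmetric = TRUE)
  # heavily penalized directions give tiny eigenvalues; only a genuinely
  # non-PSD covariance is an error
  if (!all(is.finite(ev$values)) || min(ev$values) < -1e-6 * max(ev$values))
    abort(sprintf("coefficient covariance is not positive semi-definite (condition number %.3g)",
                  max(ev$values) / max(min(abs(ev$values)), 1e-300)),
          "limnoflux_numerical_error")
  d_hat <- as.numeric(Xd %*% beta)
  se <- sqrt(pmax(rowSums((Xd %*% V) * Xd), 1e-300))
  L <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  maxstat <- with_seed(seed, {
    z <- matrix(stats::rnorm(n_draws * length(beta)), length(beta), n_draws)
    dev <- Xd %*% (L %*% z)            # grid x draws deviations
    apply(abs(dev) / se, 2, max)
  })
  crit <- stats::quantile(maxstat, level, names = FALSE, type = 8)
  lower <- d_hat - crit * se
  upper <- d_hat + crit * se
  sig <- lower > 0 | upper < 0
  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values & runs$lengths >= 2L)
  if (!length(keep)) {
    res <- empty_gam_result()
  } else {
    res <- do.call(rbind, lapply(keep, function(i) {
      i0 <- starts[i]; i1 <- ends[i]
      data.frame(method = "gam",
                 interval_start = grid[i0], interval_end = grid[i1],
                 cp_time = (grid[i0] + grid[i1]) / 2,
                 sign = sign(mean(d_hat[i0:i1])),
                 stringsAsFactors = FALSE)
    }))
    class(res) <- c("changepoint_result", "data.frame")
  }
  attr(res, "band") <- list(grid = grid, derivative = d_hat, se = se,
                            crit = crit, lower = lower, upper = upper,
                            level = level)
  res
}

empty_gam_result <- function() {
  res <- data.frame(method = character(), interval_start = numeric(),
                    interval_end = numeric(), cp_time = numeric(),
                    sign = numeric(), stringsAsFactors = FALSE)
  class(res) <- c("changepoint_result", "data.frame")
  res
}

#' Run both change-point methods on an (age-uncertain) series
#'
#' The default operating mode runs on the ensemble-median series of a
#' `flux_ensemble`; `per_member = TRUE` instead runs on every member and
#' reports the distribution of detected change times.
#'
#' @param fe a `flux_ensemble` (or a plain data frame `time`, `value`).
#' @param what flux variable when `fe` is an ensemble.
#' @param per_member run per ensemble member instead of on the median.
#' @param basis_dim,min_segment,slope_delta_min,n_draws,level,seed passed on.
#' @return list with `cumsum` and `gam` changepoint results (per-member
#'   mode: vectors of principal change times across members).
#' @export
detect_changepoints <- function(fe, what = "toc_flux", per_member = FALSE,
                                basis_dim = NULL, min_segment = 5,
                                slope_delta_min = 0.1, n_draws = 2000,
                                level = 0.95, seed = NULL) {
  one <- function(tv) {
    cs <- tryCatch(cumsum_changepoints(tv$value, tv$time, min_segment,
                                       slope_delta_min),
                   limnoflux_error = function(e) empty_cp_result("cumsum"))
    gm <- tryCatch({
      tr <- fit_gam_trend(tv$time, tv$value, basis_dim)
      derivative_changepoints(tr, n_draws, level, seed)
    }, limnoflux_error = function(e) empty_gam_result())
    list(cumsum = cs, gam = gm)
  }
  if (is.data.frame(fe)) return(one(fe))
  if (!per_member) return(one(median_flux_series(fe, what)))
  v <- fe[[what]]
  cps <- lapply(seq_len(nrow(v)), function(m) {
    o <- order(fe$age_ce[m, ])
    tv <- data.frame(time = fe$age_ce[m, o], value = v[m, o])
    r <- one(tv)
    c(cumsum = if (nrow(r$cumsum)) principal_cp(r$cumsum) else NA_real_,
      gam = if (nrow(r$gam)) principal_cp(r$gam) else NA_real_)
  })
  m <- do.call(rbind, cps)
  list(cumsum = m[, "cumsum"], gam = m[, "gam"])
}

#' Principal change point of a result
#'
#' CumSum: the change point with the largest slope change. GAM: the grid
#' time of maximal absolute derivative inside the significant intervals
#' (the steepest point of the trend), falling back to the centre of the
#' longest interval when the derivative band is unavailable.
#'
#' @param cp a `changepoint_result`.
#' @export
principal_cp <- function(cp) {
  if (!nrow(cp)) return(NA_real_)
  if (cp$method[1] == "cumsum")
    return(cp$cp_time[which.max(abs(cp$slope_after - cp$slope_before))])
  b <- attr(cp, "band")
  if (is.null(b))
    return(cp$cp_time[which.max(cp$interval_end - cp$interval_start)])
  ## principal interval = largest net fitted change (integral of the
  ## derivative); the CP is that interval's steepest point
  step <- b$grid[2] - b$grid[1]
  net <- vapply(seq_len(nrow(cp)), function(i) {
    j <- b$grid >= cp$interval_start[i] & b$grid <= cp$interval_end[i]
    abs(sum(b$derivative[j]) * step)
  }, numeric(1))
  i <- which.max(net)
  j <- which(b$grid >= cp$interval_start[i] & b$grid <= cp$interval_end[i])
  b$grid[j][which.max(abs(b$derivative[j]))]
}
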