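## Bacon-style Bayesian age-depth model.
##
## The chronology is piecewise linear over equal-thickness sections. The
## per-section accumulation rates a_i (yr cm^-1) follow a gamma prior with
## first-order memory: a_i = w a_{i-1} + (1 - w) g_i, g_i ~ Gamma(shape,
## mean = acc_mean), w ~ Beta(mean = memory_mean, strength =
## memory_strength). Dates enter through a Student-t likelihood (df = t_df);
## radiocarbon dates are compared in conventional 14C space through the
## calibration curve, so the curve error enters the likelihood scale and is
## never double counted. Sampling is Metropolis-within-Gibbs on (top age,
## log g_i, logit w) with proposal scales adapted during burn-in towards a
## 20-45% acceptance rate. Every posterior member is monotone by
## construction (a_i > 0).

#' Age-model settings
#'
#' Defaults mirror the customary settings of Bayesian accumulation
#' modelling for lake cores; all are exposed here.
#'
#' @param section_thickness section thickness, cm.
#' @param acc_mean prior mean accumulation, yr cm^-1. `NULL` = rough slope
#'   between the extreme dates, rounded to 1 significant figure.
#' @param acc_shape gamma shape of the accumulation prior.
#' @param memory_mean,memory_strength beta prior on the memory w
#'   (mean/strength parameterization).
#' @param t_df Student-t degrees of freedom of the dating likelihood.
#' @param n_iter,burn_in MCMC iterations and burn-in.
#' @param n_members posterior members kept after thinning.
#' @param collection_year core-collection year CE (time datum).
#' @param exclude_intervals optional list of `c(top, bottom)` depth pairs
#'   (cm) treated as instantaneous event layers: collapsed before modelling
#'   and re-expanded (flat age) in the output.
#' @export
age_model_settings <- function(section_thickness = 5, acc_mean = NULL,
                               acc_shape = 1.5, memory_mean = 0.7,
                               memory_strength = 4, t_df = 6,
                               n_iter = 60000, burn_in = 10000,
                               n_members = 1000, collection_year = 2015,
                               exclude_intervals = NULL) {
  list(section_thickness = section_thickness, acc_mean = acc_mean,
       acc_shape = acc_shape, memory_mean = memory_mean,
       memory_strength = memory_strength, t_df = t_df, n_iter = n_iter,
       burn_in = burn_in, n_members = n_members,
       collection_year = collection_year,
       exclude_intervals = exclude_intervals)
}

## depth -> effective depth after collapsing excluded event intervals
collapse_depth <- function(d, intervals) {
  if (is.null(intervals) || !length(intervals)) return(d)
  out <- d
  for (iv in intervals) {
    lo <- min(iv); hi <- max(iv)
    out <- out - pmin(pmax(d - lo, 0), hi - lo)
  }
  out
}

## effective depth -> real depth (inverse of collapse_depth)
expand_depth <- function(e, intervals) {
  if (is.null(intervals) || !length(intervals)) return(e)
  out <- e
  for (iv in intervals[order(vapply(intervals, min, numeric(1)))]) {
    lo <- min(iv); hi <- max(iv)
    elo <- collapse_depth(lo, intervals)
    out <- ifelse(out > elo, out + (hi - lo), out)
  }
  out
}

#' Fit the Bayesian age-depth model
#'
#' @param dates a [date_table()].
#' @param curve a [calibration_curve()]; required with radiocarbon dates.
#' @param settings an [age_model_settings()] list.
#' @param seed RNG seed.
#' @param core_depth optional bottom depth, cm (default: deepest date,
#'   rounded up to a whole section).
#' @return an `age_depth_ensemble`: depth grid (cm), member x depth matrix
#'   of ages (years before collection), memory draws, and diagnostics
#'   (acceptance rates, split-chain Rhat on the mean age with a
#'   non-convergence flag at Rhat > 1.1).
#' @export
fit_age_model <- function(dates, curve = NULL,
                          settings = age_model_settings(), seed = NULL,
                          core_depth = NULL) {
  validate_date_table(dates)
  s <- settings
  use <- !dates$excluded
  d <- dates[use, , drop = FALSE]
  iv <- s$exclude_intervals
  if (is.null(core_depth)) core_depth <- max(dates$depth)
  eff_bottom <- collapse_depth(core_depth, iv)
  K <- max(1L, ceiling(eff_bottom / s$section_thickness))
  thk <- s$section_thickness
  eff_depth <- collapse_depth(d$depth, iv)
  if (any(eff_depth > K * thk + 1e-9))
    abort("core span does not cover all non-excluded dates", "limnoflux_data_error")

  ## observed ages in the internal datum (years before collection)
  is_c14 <- d$type == "radiocarbon"
  if (any(is_c14) && is.null(curve))
    abort("radiocarbon dates require a calibration curve", "limnoflux_data_error")
  obs_yb <- ifelse(is_c14, NA_real_, s$collection_year - d$age)
  offset_1950 <- s$collection_year - 1950  # yb -> cal BP shift

  ## impossible stratigraphy: calendar dates reversed beyond 5 sigma
  cal <- which(!is_c14)
  if (length(cal) > 1L) {
    o <- cal[order(eff_depth[cal])]
    for (i in seq_len(length(o) - 1L)) for (j in (i + 1L):length(o)) {
      a <- o[i]; b <- o[j]
      gap <- obs_yb[a] - obs_yb[b]  # shallower older than deeper => positive
      if (gap > 5 * sqrt(d$error[a]^2 + d$error[b]^2))
        abort(sprintf("calendar dates %s and %s force an age reversal beyond 5 sigma",
                      d$labID[a], d$labID[b]), "limnoflux_data_error")
    }
  }

  ## rough-slope default for acc_mean (1 significant figure)
  if (is.null(s$acc_mean)) {
    if (nrow(d) >= 2L && diff(range(eff_depth)) > 0) {
      rough_age <- ifelse(is_c14, d$age - offset_1950 + 2 * offset_1950, obs_yb)
      # radiocarbon rough age: treat 14C age BP as cal BP, shift to yb
      rough_age[is_c14] <- d$age[is_c14] + offset_1950
      sl <- abs(diff(range(rough_age)) / diff(range(eff_depth)))
      s$acc_mean <- max(signif(sl, 1), 0.1)
    } else s$acc_mean <- 10
  }

  grid_eff <- seq(0, K * thk, by = thk)
  grid_real <- expand_depth(grid_eff, iv)
  if (!is.null(iv) && length(iv)) {
    # add event edges so interpolation is flat across the collapsed layer
    edges <- unlist(lapply(iv, function(x) c(min(x), max(x))))
    grid_real <- sort(unique(c(grid_real, edges)))
    grid_eff <- collapse_depth(grid_real, iv)
  }

  shape <- s$acc_shape; rate <- s$acc_shape / s$acc_mean
  mm <- s$memory_mean; ms <- s$memory_strength
  a_from <- function(g, w, a_old = NULL, from = 1L) {
    # a_1 = g_1; a_i = w a_{i-1} + (1-w) g_i. When only g[from] changed,
    # entries before `from` are reused from a_old.
    a <- if (is.null(a_old)) numeric(length(g)) else a_old
    for (i in max(from, 1L):length(g))
      a[i] <- if (i == 1L) g[1] else w * a[i - 1] + (1 - w) * g[i]
    a
  }

  ## --- prior-only mode: no usable dates -> sample the prior directly
  if (nrow(d) == 0L) {
    ens <- with_seed(seed, {
      M <- s$n_members
      ages <- matrix(NA_real_, M, length(grid_eff))
      wdr <- stats::rbeta(M, mm * ms, (1 - mm) * ms)
      for (m in seq_len(M)) {
        g <- stats::rgamma(K, shape, rate)
        a <- numeric(K); a[1] <- g[1]
        if (K > 1) for (i in 2:K) a[i] <- wdr[m] * a[i - 1] + (1 - wdr[m]) * g[i]
        ages[m, ] <- stats::approx(seq(0, K * thk, by = thk),
                                   c(0, cumsum(a * thk)), xout = grid_eff,
                                   ties = "ordered")$y
      }
      list(ages = ages, w = wdr, diag = list(mode = "prior"))
    })
    return(structure(list(depth = grid_real, ages = ens$ages, w = ens$w,
                          collection_year = s$collection_year,
                          diagnostics = ens$diag, settings = s),
                     class = "age_depth_ensemble"))
  }

  ## precompute section index / partial thickness per date
  sec <- pmin(pmax(ceiling(eff_depth / thk), 1L), K)
  frac <- eff_depth - (sec - 1L) * thk
  i_cal <- which(!is_c14); i_c14 <- which(is_c14)
  err_cal <- d$error[i_cal]; obs_cal <- obs_yb[i_cal]
  err2_c14 <- d$error[i_c14]^2; obs_c14 <- d$age[i_c14]
  if (length(i_c14)) {
    # fast linear-interpolation tables for the calibration curve
    cv_x <- curve$cal_bp
    cv_mu <- curve$c14_age
    cv_sg <- curve$error
    cv_dmu <- diff(cv_mu) / diff(cv_x)
    cv_dsg <- diff(cv_sg) / diff(cv_x)
    cv_lo <- cv_x[1]; cv_hi <- cv_x[length(cv_x)]
  }

  ## date ages are linear in the accumulations: m = theta0 + A %*% a
  A <- matrix(0, nrow(d), K)
  for (jj in seq_len(nrow(d))) {
    if (sec[jj] > 1L) A[jj, seq_len(sec[jj] - 1L)] <- thk
    A[jj, sec[jj]] <- frac[jj]
  }
  tdf <- s$t_df
  log_err_cal <- log(err_cal)
  n_curve <- if (length(i_c14)) length(cv_x) - 1L else 0L

  log_lik <- function(theta0, a) {
    m <- theta0 + A %*% a
    ll <- 0
    if (length(i_cal)) {
      z <- (obs_cal - m[i_cal]) / err_cal
      ll <- sum(stats::dt(z, df = tdf, log = TRUE) - log_err_cal)
    }
    if (length(i_c14)) {
      cal_bp <- m[i_c14] - offset_1950
      if (any(cal_bp < cv_lo | cal_bp > cv_hi)) return(-Inf)
      j <- pmin.int(findInterval(cal_bp, cv_x), n_curve)
      dx <- cal_bp - cv_x[j]
      mu <- cv_mu[j] + dx * cv_dmu[j]
      sg <- sqrt(err2_c14 + (cv_sg[j] + dx * cv_dsg[j])^2)
      z <- (obs_c14 - mu) / sg
      ll <- ll + sum(stats::dt(z, df = tdf, log = TRUE) - log(sg))
    }
    ll
  }
  ## log prior pieces; u = log g (Jacobian term + u), v = logit w
  lp_gam_term <- function(u_k) stats::dgamma(exp(u_k), shape, rate, log = TRUE) + u_k
  lp_w_term <- function(v) {
    w <- stats::plogis(v)
    stats::dbeta(w, mm * ms, (1 - mm) * ms, log = TRUE) + log(w) + log(1 - w)
  }

  res <- with_seed(seed, {
    ## initialization: slope through extreme dates, top age from shallowest
    rough_yb <- obs_yb
    rough_yb[is_c14] <- d$age[is_c14] + offset_1950
    o <- order(eff_depth)
    if (nrow(d) >= 2L && diff(range(eff_depth)) > 0) {
      sl <- (rough_yb[o[length(o)]] - rough_yb[o[1]]) / diff(range(eff_depth))
      sl <- max(sl, s$acc_mean / 10)
    } else sl <- s$acc_mean
    u <- rep(log(sl), K)
    v <- stats::qlogis(min(max(mm, 0.05), 0.95))
    theta0 <- rough_yb[o[1]] - sl * eff_depth[o[1]]
    g <- exp(u); w <- stats::plogis(v)
    a_cur <- a_from(g, w)
    lik <- log_lik(theta0, a_cur)
    if (!is.finite(lik)) { theta0 <- 0; lik <- log_lik(theta0, a_cur) }
    pri_u <- vapply(u, lp_gam_term, numeric(1))
    pri_v <- lp_w_term(v)

    n_par <- K + 2L
    sc <- c(rep(0.3, K), 0.3, max(mean(d$error), 1))  # u_k, v, theta0
    acc_n <- att_n <- numeric(n_par)
    keep_from <- s$burn_in + 1L
    keep_idx <- unique(round(seq(keep_from, s$n_iter, length.out = s$n_members)))
    ages_kept <- matrix(NA_real_, length(keep_idx), length(grid_eff))
    w_kept <- numeric(length(keep_idx))
    mean_age_chain <- numeric(length(keep_idx))
    ki <- 1L

    for (it in seq_len(s$n_iter)) {
      for (p in seq_len(n_par)) {
        att_n[p] <- att_n[p] + 1
        step <- stats::rnorm(1, 0, sc[p])
        if (p <= K) {
          u2k <- u[p] + step
          g2 <- g; g2[p] <- exp(u2k)
          a2 <- a_from(g2, w, a_cur, from = p)
          lik2 <- log_lik(theta0, a2)
          pri2 <- lp_gam_term(u2k)
          if (is.finite(lik2) &&
              log(stats::runif(1)) < (lik2 + pri2) - (lik + pri_u[p])) {
            u[p] <- u2k; g <- g2; a_cur <- a2; lik <- lik2; pri_u[p] <- pri2
            acc_n[p] <- acc_n[p] + 1
          }
        } else if (p == K + 1L) {
          v2 <- v + step
          w2 <- stats::plogis(v2)
          a2 <- a_from(g, w2)
          lik2 <- log_lik(theta0, a2)
          pri2 <- lp_w_term(v2)
          if (is.finite(lik2) &&
              log(stats::runif(1)) < (lik2 + pri2) - (lik + pri_v)) {
            v <- v2; w <- w2; a_cur <- a2; lik <- lik2; pri_v <- pri2
            acc_n[p] <- acc_n[p] + 1
          }
        } else {
          t2 <- theta0 + step
          lik2 <- log_lik(t2, a_cur)
          if (is.finite(lik2) && log(stats::runif(1)) < lik2 - lik) {
            theta0 <- t2; lik <- lik2
            acc_n[p] <- acc_n[p] + 1
          }
        }
      }
      if (it <= s$burn_in && it %% 50L == 0L) {
        r <- acc_n / pmax(att_n, 1)
        sc <- sc * exp(1.2 * (r - 0.3))
        sc <- pmin(pmax(sc, 1e-4), 1e4)
        acc_n[] <- 0; att_n[] <- 0
      }
      if (ki <= length(keep_idx) && it == keep_idx[ki]) {
        cum <- theta0 + c(0, cumsum(a_cur * thk))
        ages_kept[ki, ] <- stats::approx(seq(0, K * thk, by = thk), cum,
                                         xout = grid_eff, ties = "ordered")$y
        w_kept[ki] <- stats::plogis(v)
        mean_age_chain[ki] <- mean(cum)
        ki <- ki + 1L
      }
    }
    list(ages = ages_kept, w = w_kept, acc = acc_n / pmax(att_n, 1),
         chain = mean_age_chain)
  })

  rhat <- split_rhat(res$chain)
  diag <- list(mode = "posterior", acceptance = res$acc, rhat = rhat,
               converged = is.na(rhat) || rhat <= 1.1,
               acc_mean_used = s$acc_mean, n_sections = K)
  if (!isTRUE(diag$converged))
    warning(sprintf("age model may not have converged (split Rhat = %.3f)", rhat))
  structure(list(depth = grid_real, ages = res$ages, w = res$w,
                 collection_year = s$collection_year,
                 diagnostics = diag, settings = s),
            class = "age_depth_ensemble")
}

## Split-chain potential scale reduction on a single scalar chain.
split_rhat <- function(x) {
  n <- floor(length(x) / 2) * 2
  if (n < 8) return(NA_real_)
  h <- matrix(x[seq_len(n)], ncol = 2)
  m <- colMeans(h); v <- apply(h, 2, stats::var)
  W <- mean(v); B <- nrow(h) * stats::var(m)
  if (W <= 0) return(1)
  sqrt(((nrow(h) - 1) / nrow(h) * W + B / nrow(h)) / W)
}

#' Interpolate ensemble ages at arbitrary depths
#'
#' Piecewise-linear within each posterior member; refuses extrapolation.
#'
#' @param ens an `age_depth_ensemble`.
#' @param depths depths, cm (within the modelled span).
#' @param units `"yb"` (years before collection) or `"CE"`.
#' @return member x depth matrix of ages.
#' @export
ensemble_ages_at <- function(ens, depths, units = c("yb", "CE")) {
  units <- match.arg(units)
  if (any(depths < min(ens$depth) - 1e-9 | depths > max(ens$depth) + 1e-9))
    abort(sprintf("depth outside the modelled span [%g, %g]",
                  min(ens$depth), max(ens$depth)), "limnoflux_range_error")
  out <- t(apply(ens$ages, 1, function(a)
    stats::approx(ens$depth, a, xout = depths, ties = "ordered")$y))
  if (length(depths) == 1L) out <- matrix(out, ncol = 1L)
  if (units == "CE") out <- ens$collection_year - out
  out
}

#' Sedimentation rate per ensemble member between consecutive depths
#'
#' SR over `[d_j, d_{j+1}]` is `(d_{j+1} - d_j) / (age_{j+1} - age_j)` per
#' member, cm yr^-1; strictly positive for monotone members.
#'
#' @param ens an `age_depth_ensemble`.
#' @param depths >= 2 strictly increasing depths, cm.
#' @return member x interval matrix of sedimentation rates.
#' @export
sed_rate_ensemble <- function(ens, depths) {
  if (length(depths) < 2L)
    abort("need at least 2 depths for a sedimentation rate", "limnoflux_parameter_error")
  if (any(diff(depths) <= 0))
    abort("depths must be strictly increasing", "limnoflux_parameter_error")
  ages <- ensemble_ages_at(ens, depths, "yb")
  da <- ages[, -1L, drop = FALSE] - ages[, -ncol(ages), drop = FALSE]
  if (any(da <= 0))
    abort("zero or negative age increment over an interval (degenerate)",
          "limnoflux_degenerate_error")
  dd <- diff(depths)
  sweep(1 / da, 2, dd, `*`)
}

#' Summarize an ensemble on its depth grid
#'
#' @param ens an `age_depth_ensemble`.
#' @param probs quantiles reported besides the median.
#' @param units `"yb"` or `"CE"`.
#' @return data frame: depth, median and the requested quantiles.
#' @export
ensemble_summary <- function(ens, probs = c(0.025, 0.975),
                             units = c("yb", "CE")) {
  units <- match.arg(units)
  a <- ens$ages
  if (units == "CE") a <- ens$collection_year - a
  q <- apply(a, 2, stats::quantile, probs = probs)
  out <- data.frame(depth = ens$depth, median = apply(a, 2, stats::median))
  for (i in seq_along(probs)) out[[sprintf("q%g", 100 * probs[i])]] <- q[i, ]
  out
}
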