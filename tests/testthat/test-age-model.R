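# Radiocarbon calibration and the Bayesian age-depth model.

test_that("calibration density is a normalized Gaussian on an identity curve", {
  crv <- identity_calibration_curve(error = 1e-6)
  cd <- calibrate_date(500, 20, crv)
  # closed form: N(500, 20^2) on the grid
  ref <- dnorm(cd$cal_bp, 500, 20)
  ref <- ref / sum(diff(cd$cal_bp) * (head(ref, -1) + tail(ref, -1)) / 2)
  expect_lt(max(abs(cd$density - ref)), 1e-6)
  expect_equal(cd$cal_bp[which.max(cd$density)], 500)
  integral <- sum(diff(cd$cal_bp) *
                    (head(cd$density, -1) + tail(cd$density, -1)) / 2)
  expect_equal(integral, 1, tolerance = 1e-8)
  expect_error(calibrate_date(1e6, 20, crv), class = "limnoflux_calibration_error")
})

test_that("two-segment curve mode matches an exhaustive grid search", {
  # steep then shallow curve; oracle scans a 1-yr grid of the same kernel
  cal <- seq(0, 2000, by = 1)
  c14 <- ifelse(cal < 1000, 2 * cal, 2000 + 0.5 * (cal - 1000))
  crv <- calibration_curve(cal, c14, 10)
  cd <- calibrate_date(1500, 15, crv)
  oracle <- cal[which.max(dnorm(1500, c14, sqrt(15^2 + 10^2)))]
  expect_equal(cd$cal_bp[which.max(cd$density)], oracle, tolerance = 1)
})

test_that("a single precise calendar date pins the core top", {
  dt <- date_table("top", 2000, 0.1, 0, "calendar")
  st <- age_model_settings(section_thickness = 5, acc_mean = 10,
                           n_iter = 2000, burn_in = 500, n_members = 200)
  ens <- fit_age_model(dt, settings = st, seed = 3, core_depth = 5)
  med_top <- 2015 - median(ens$ages[, 1])
  expect_equal(med_top, 2000, tolerance = 0.5)
})

test_that("posterior recovers a constant-accumulation truth", {
  ch <- const_chron(acc = 10, n_sections = 20)
  depths <- c(15, 31, 47, 63, 79, 95)
  dt <- simulate_dates(ch, depths, 5, "calendar", seed = 11)
  ens <- fit_age_model(dt, settings = fast_settings(), seed = 12,
                       core_depth = 100)
  # every member monotone: a violation is a bug, not a warning
  expect_true(all(apply(ens$ages, 1, function(a) all(diff(a) >= 0))))
  s <- ensemble_summary(ens)
  truth <- chron_age(ch, ens$depth, "yb")
  med_at <- approx(ens$depth, s$median, xout = depths)$y
  expect_true(all(abs(med_at - chron_age(ch, depths, "yb")) <=
                    0.05 * chron_age(ch, depths, "yb")))
  expect_gte(mean(truth >= s[["q2.5"]] & truth <= s[["q97.5"]]), 0.9)
})

test_that("a 3-sigma reversal is absorbed by the t-likelihood", {
  dt <- date_table(c("a", "b"), c(1900, 1930), c(10, 10), c(20, 40),
                   "calendar")   # deeper date younger by 3 sigma
  st <- age_model_settings(acc_mean = 5, n_iter = 1500, burn_in = 400,
                           n_members = 150)
  ens <- fit_age_model(dt, settings = st, seed = 5, core_depth = 50)
  expect_true(all(apply(ens$ages, 1, function(a) all(diff(a) >= 0))))
  # beyond 5 sigma it is a data error
  dt2 <- date_table(c("a", "b"), c(1800, 1950), c(10, 10), c(20, 40),
                    "calendar")
  expect_error(fit_age_model(dt2, settings = st, core_depth = 50),
               class = "limnoflux_data_error")
})

test_that("prior-sampling mode reproduces the accumulation prior mean", {
  dt <- date_table("x", 2000, 5, 10, "calendar", excluded = TRUE)
  st <- age_model_settings(acc_mean = 10, acc_shape = 1.5,
                           n_members = 2000)
  ens <- fit_age_model(dt, settings = st, seed = 9, core_depth = 50)
  expect_identical(ens$diagnostics$mode, "prior")
  # core-average accumulation from member slopes
  acc <- (ens$ages[, ncol(ens$ages)] - ens$ages[, 1]) / 50
  expect_lt(abs(mean(acc) - 10), 2 * sd(acc) / sqrt(length(acc)))
})

test_that("ensemble interpolation and sedimentation rates are exact", {
  ens <- linear_ensemble(acc = 10)
  # boundary depth returns the stored age; midpoint = mean of endpoints
  expect_equal(ensemble_ages_at(ens, 20)[, 1], rep(200, 5))
  expect_equal(ensemble_ages_at(ens, 25)[, 1], rep(250, 5))
  expect_error(ensemble_ages_at(ens, 101), class = "limnoflux_range_error")
  sr <- sed_rate_ensemble(ens, c(0, 10, 30, 100))
  expect_equal(as.numeric(sr), rep(0.1, length(sr)))
  expect_true(all(sr > 0))
  # doubling all accumulations halves every SR (oracle: scaled truth)
  ens2 <- ens; ens2$ages <- ens$ages * 2
  expect_equal(sed_rate_ensemble(ens2, c(0, 10, 30, 100)),
               sr / 2, tolerance = 1e-12)
  expect_error(sed_rate_ensemble(ens, 10), class = "limnoflux_parameter_error")
})

test_that("event-layer intervals collapse to instantaneous deposition", {
  dt <- date_table(c("a", "b"), c(2000, 1800), c(2, 2), c(0, 47), "calendar")
  st <- age_model_settings(acc_mean = 5, n_iter = 1500, burn_in = 400,
                           n_members = 150,
                           exclude_intervals = list(c(20, 27)))
  ens <- fit_age_model(dt, settings = st, seed = 6, core_depth = 47)
  a <- ensemble_ages_at(ens, c(20, 27))
  expect_equal(a[, 1], a[, 2], tolerance = 1e-9)  # flat across the event
  expect_true(all(apply(ens$ages, 1, function(x) all(diff(x) >= -1e-9))))
})
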