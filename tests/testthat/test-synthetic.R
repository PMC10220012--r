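# Synthetic core generator: parameter recovery against the stated models.

test_that("chronology degenerate limits behave exactly", {
  # full memory: every section shares a_1, age-depth exactly linear
  ch <- simulate_chronology(10, 5, 10, memory = 1, seed = 2)
  expect_lt(max(abs(diff(ch$acc))), 1e-12)
  expect_equal(diff(ch$yb), rep(ch$acc[1] * 5, 10), tolerance = 1e-12)
  # zero-variance gamma: exactly acc_mean yr/cm
  ch2 <- const_chron(acc = 10)
  expect_equal(chron_age(ch2, 50, "CE"), 2015 - 500, tolerance = 0.5)
  # strict monotonicity in age with depth, across seeds
  for (s in 1:20) {
    chs <- simulate_chronology(8, 5, 12, memory = 0.7, seed = s)
    expect_true(all(diff(chs$yb) > 0))
  }
  expect_error(simulate_chronology(0, 5, 10), class = "limnoflux_parameter_error")
  expect_error(simulate_chronology(5, 5, -1), class = "limnoflux_parameter_error")
})

test_that("core-average accumulation is unbiased (Monte-Carlo oracle)", {
  # oracle: direct Monte-Carlo of the stated recursion, independent code
  oracle_draw <- function(seed) {
    set.seed(seed + 10000L)
    g <- rgamma(8, shape = 1.5, rate = 1.5 / 10)
    a <- numeric(8); a[1] <- g[1]
    for (i in 2:8) a[i] <- 0.7 * a[i - 1] + 0.3 * g[i]
    mean(a)
  }
  sim <- vapply(1:1000, function(s)
    mean(simulate_chronology(8, 5, 10, 1.5, 0.7, seed = s)$acc), numeric(1))
  orc <- vapply(1:1000, oracle_draw, numeric(1))
  se <- sd(sim) / sqrt(length(sim))
  expect_lt(abs(mean(sim) - 10), 2 * se + 2 * sd(orc) / sqrt(length(orc)))
  expect_lt(abs(mean(sim) - mean(orc)), 3 * sqrt(var(sim) / 1000 + var(orc) / 1000))
})

test_that("simulated dates follow the stated sampling model", {
  ch <- const_chron()
  # noiseless limit
  d0 <- simulate_dates(ch, c(10, 50), c(1e-9, 1e-9), "calendar", seed = 1)
  expect_equal(d0$age, chron_age(ch, c(10, 50), "CE"), tolerance = 1e-6)
  # z-scores standard normal: mean over 500 draws within +-2/sqrt(500)
  z <- vapply(1:500, function(s) {
    (simulate_dates(ch, 40, 5, "calendar", seed = s)$age -
       chron_age(ch, 40, "CE")) / 5
  }, numeric(1))
  expect_lt(abs(mean(z)), 2 / sqrt(500))
  # radiocarbon through the identity curve lands on the true cal age
  crv <- identity_calibration_curve()
  dr <- simulate_dates(ch, 80, 1e-9, "radiocarbon", crv, seed = 2)
  expect_equal(dr$age, 1950 - chron_age(ch, 80, "CE"), tolerance = 1e-5)
  expect_error(simulate_dates(ch, -1, 5, "calendar"),
               class = "limnoflux_range_error")
  expect_error(simulate_dates(ch, 10, 0, "calendar"),
               class = "limnoflux_parameter_error")
})

test_that("date z-scores pass a KS normality screen in >=95% of batches", {
  ch <- const_chron()
  depths <- seq(2, 98, length.out = 200)
  truth <- chron_age(ch, depths, "CE")
  pass <- vapply(1:100, function(b) {
    obs <- simulate_dates(ch, depths, 5, "calendar", seed = 1000 + b)$age
    suppressWarnings(stats::ks.test((obs - truth) / 5, "pnorm")$p.value) > 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("proxy regimes reproduce configured levels and steps", {
  ch <- const_chron()
  # noiseless step outside the record span: constant at pre_level
  r <- list(regime("CN", change_year = 2100, shape = "step",
                   pre_level = 12, post_level = 5, noise_sd = 0))
  pr <- simulate_proxies(ch, r, seed = 1)
  expect_equal(pr$CN, rep(12, nrow(pr)))
  # step recovery over 200 replicates within 2 SE (Monte-Carlo oracle)
  r2 <- list(regime("CN", 1950, "step", 12, 8, noise_sd = 0.5, ar1 = 0.3))
  diffs <- vapply(1:200, function(s) {
    p <- simulate_proxies(ch, r2, seed = s)
    tru <- attr(p, "truth")$age_ce
    mean(p$CN[tru >= 1950]) - mean(p$CN[tru < 1950])
  }, numeric(1))
  expect_lt(abs(mean(diffs) - (-4)), 2 * sd(diffs) / sqrt(200))
  # unknown regime variable is a schema error
  expect_error(regime("unobtainium", 1950, "step", 1),
               class = "limnoflux_schema_error")
})

test_that("flux-level regimes survive the percent-space round trip", {
  # the flagship organic step: 14 -> 66 g m^-2 yr^-1 at 1970
  ch <- const_chron()
  pr <- simulate_proxies(ch, default_regimes(), seed = 7)
  tru <- attr(pr, "truth")
  fl <- pr$density * tru$sed_rate * pr$TOC / 100 * 1e4
  expect_equal(mean(fl[tru$age_ce < 1960]), 14, tolerance = 0.2 * 14)
  expect_equal(mean(fl[tru$age_ce > 1980]), 66, tolerance = 0.2 * 66)
  # closure invariants
  expect_true(all(pr$TOC >= 0 & pr$TIC >= 0 & pr$TOC + pr$TIC <= 100 + 1e-9))
  expect_true(all(abs(pr$sand + pr$silt + pr$clay - 100) < 0.5))
  expect_true(all(pr$density > 0))
})

test_that("diatom counts close exactly and carry the planktonic rise", {
  ch <- const_chron()
  di <- simulate_diatoms(ch, valves_per_sample = 400, seed = 1)
  expect_true(all(rowSums(di[, grep("^taxon", names(di))]) == 400))
  # symmetry: huge concentration, no change in span before change_year
  di2 <- simulate_diatoms(ch, n_taxa = 5, planktonic_taxa = 1,
                          change_year = 2100, concentration = 1e9,
                          valves_per_sample = 5000, plank_pre = 0.2,
                          plank_post = 0.2, seed = 2)
  rel <- as.matrix(di2[, grep("^taxon", names(di2))]) / 5000
  # taxon 1 target share 0.2 and the 4 benthic share 0.8 by decaying ranks
  expect_equal(mean(rel[, 1]), 0.2, tolerance = 0.02)
  # planktonic share rises after the change year (100 seeds)
  rises <- vapply(1:100, function(s) {
    d <- simulate_diatoms(ch, change_year = 1950, seed = s)
    ds <- diatom_summaries(d)
    mean(ds$planktonic_fraction[d$age_ce > 1950]) >
      mean(ds$planktonic_fraction[d$age_ce < 1950])
  }, logical(1))
  expect_gte(mean(rises), 0.99)
  expect_error(simulate_diatoms(ch, n_taxa = 4, planktonic_taxa = 9),
               class = "limnoflux_parameter_error")
})
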