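# PCA variants and diatom summaries.

test_that("standardized PCA agrees with an independent eigendecomposition", {
  set.seed(10)
  X <- matrix(rnorm(100), 20, 5)
  colnames(X) <- paste0("v", 1:5)
  p <- standardized_pca(X)
  e <- eigen(cor(X), symmetric = TRUE)     # independent oracle path
  expect_lt(max(abs(p$varfrac - e$values / sum(e$values))), 1e-8)
  for (k in 1:5)
    expect_lt(min(max(abs(p$loadings[, k] - e$vectors[, k])),
                  max(abs(p$loadings[, k] + e$vectors[, k]))), 1e-8)
  # orthonormal loadings
  expect_lt(max(abs(crossprod(p$loadings) - diag(5))), 1e-10)
  # two perfectly correlated variables -> PC1 carries everything
  Y <- cbind(a = 1:10, b = 2 * (1:10) + 3)
  expect_equal(standardized_pca(Y)$varfrac[1], 1, tolerance = 1e-10)
  # variance fractions non-increasing, sum <= 1
  expect_true(all(diff(p$varfrac) <= 1e-12))
  expect_lte(sum(p$varfrac), 1 + 1e-12)
  expect_message(standardized_pca(cbind(X, const = 1)), "zero-variance")
})

test_that("Hellinger transform and filter behave as specified", {
  m <- matrix(c(9, 16, 25, 0, 10, 10), 3, 2, byrow = TRUE)
  colnames(m) <- c("t1", "t2")
  h <- hellinger_pca(m, min_occurrences = 1)
  H <- attr(h, "hellinger")
  expect_equal(H[1, ], c(t1 = 0.6, t2 = 0.8))
  expect_equal(rowSums(H^2), rep(1, 3), tolerance = 1e-12)
  # a taxon at 0.5% everywhere is excluded under the 1% default
  big <- cbind(common = rep(995, 5), rare = rep(5, 5), other = rep(200, 5))
  hb <- hellinger_pca(big)
  expect_false("rare" %in% attr(hb, "taxa_retained"))
  expect_true(all(c("common", "other") %in% attr(hb, "taxa_retained")))
  # single-occurrence taxa need min_occurrences samples
  one <- cbind(a = c(100, 100, 100), b = c(50, 0, 0), c = c(10, 20, 30))
  expect_false("b" %in% attr(hellinger_pca(one), "taxa_retained"))
  expect_error(hellinger_pca(cbind(a = rep(1, 3)), min_abundance = 2),
               class = "limnoflux_filter_error")
})

test_that("Hellinger PCA agrees with the community-ecology reference", {
  set.seed(3)
  m <- matrix(rpois(60, 40) + 1, 10, 6)
  colnames(m) <- paste0("t", 1:6)
  ours <- hellinger_pca(m, min_abundance = 0, min_occurrences = 1)
  ref <- vegan::rda(vegan::decostand(m, "hellinger"))
  ref_frac <- ref$CA$eig / sum(ref$CA$eig)
  expect_equal(unname(ours$varfrac[1:3]), unname(ref_frac[1:3]),
               tolerance = 1e-8)
})

test_that("PPCA reduces to PCA on complete data and recovers factors", {
  set.seed(11)
  X <- matrix(rnorm(120), 24, 5)
  p_ref <- standardized_pca(X)
  p_em <- ppca_missing(scale(X), n_components = 2, tol = 1e-11)
  expect_lt(max(abs(p_em$varfrac[1:2] - p_ref$varfrac[1:2])), 1e-6)
  # one-factor recovery with 10% missing, |corr| > 0.95 over 20 seeds
  ok <- vapply(1:20, function(s) {
    set.seed(s)
    L <- rnorm(6); Z <- rnorm(100)
    Y <- outer(Z, L) + matrix(rnorm(600, 0, 0.3), 100, 6)
    Y[sample(600, 60)] <- NA
    abs(cor(ppca_missing(Y, 1)$loadings[, 1], L)) > 0.95
  }, logical(1))
  expect_gte(mean(ok), 0.95)
  # all-missing column violates the precondition
  Z <- matrix(rnorm(40), 10, 4); Z[, 2] <- NA
  expect_error(ppca_missing(Z, 1), class = "limnoflux_precondition_error")
})

test_that("age-uncertain PCA collapses correctly without age uncertainty", {
  # identical members: median scores equal plain PCA on the binned data
  depths <- seq(2, 98, by = 2)
  n <- length(depths)
  ages <- matrix(rep(2015 - depths * 10, each = 3), 3, byrow = FALSE)
  set.seed(5)
  v1 <- sin(depths / 10) + rnorm(n, 0, 0.1)
  v2 <- sin(depths / 10) + rnorm(n, 0, 0.1)
  v3 <- rnorm(n)
  sl <- list(au_series("a", ages, v1), au_series("b", ages, v2),
             au_series("c", ages, v3))
  ap <- age_uncertain_pca(sl, bin_width = 50, t0 = 1000, t1 = 2015,
                          n_members_used = 4, n_components = 2, seed = 1)
  breaks <- seq(1000, 2015 + 49, by = 50)
  X <- vapply(list(v1, v2, v3), function(v)
    tapply(v, findInterval(ages[1, ], breaks, rightmost.closed = TRUE), mean),
    numeric(length(unique(findInterval(ages[1, ], breaks, rightmost.closed = TRUE)))))
  p_ref <- standardized_pca(X)
  med <- ap$summary[ap$summary$component == 1, "median"]
  med <- med[is.finite(med)]
  ref1 <- p_ref$scores[, 1] / sd(p_ref$scores[, 1])
  got <- med / sd(med)
  expect_lt(min(max(abs(got - ref1)), max(abs(got + ref1))), 0.15)
  # bands nested: 95% HDI contains the 50% HDI
  s2 <- ap$summary
  ok <- is.finite(s2$hdi50_lo)
  expect_true(all(s2$hdi95_lo[ok] <= s2$hdi50_lo[ok] + 1e-9))
  expect_true(all(s2$hdi95_hi[ok] >= s2$hdi50_hi[ok] - 1e-9))
  # single variable: trivially explains everything
  ap1 <- age_uncertain_pca(sl[1], bin_width = 50, t0 = 1000, t1 = 2015,
                           n_members_used = 3, seed = 2)
  expect_true(all(ap1$varfrac[, 1] == 1))
})

test_that("sign alignment makes member sign flips irrelevant", {
  set.seed(6)
  depths <- seq(2, 98, by = 2)
  n <- length(depths)
  base <- 2015 - depths * 10
  ages <- rbind(base, base + rnorm(n, 0, 5), base + rnorm(n, 0, 5))
  v <- depths / 50 + rnorm(n, 0, 0.1)
  sl <- list(au_series("a", ages, v), au_series("b", ages, v + rnorm(n, 0, 0.1)))
  ap <- age_uncertain_pca(sl, bin_width = 100, t0 = 1000, t1 = 2015,
                          n_members_used = 3, seed = 3)
  # loadings of each draw aligned with the first draw's
  for (j in 2:3)
    expect_gte(sum(ap$loadings[j, , 1] * ap$loadings[1, , 1], na.rm = TRUE), 0)
})

test_that("diatom summaries follow the spike arithmetic", {
  d <- data.frame(depth = 1, age_ce = 2000, tA = 200, tB = 100,
                  cysts = 0, microspheres = 100, spike = 1e5, mass_g = 0.1)
  class(d) <- c("diatom_counts", "data.frame")
  s <- diatom_summaries(d, planktonic = "tA")
  expect_equal(s$valves_per_g, 3.0e6)     # 300 * (1e5/100) / 0.1
  expect_equal(s$cd_ratio, 0)
  expect_equal(rowSums(s$rel), 1, tolerance = 1e-12)
  expect_equal(s$planktonic_fraction, 200 / 300)
  d$microspheres <- 0
  expect_error(diatom_summaries(d), class = "limnoflux_data_error")
})

test_that("hdi intervals are shortest and properly nested", {
  set.seed(12)
  x <- rnorm(5000)
  h95 <- hdi_interval(x, 0.95); h50 <- hdi_interval(x, 0.50)
  expect_lt(h95[1], h50[1]); expect_gt(h95[2], h50[2])
  expect_equal(h95, qnorm(c(0.025, 0.975)), tolerance = 0.15)
  expect_gte(mean(x >= h50[1] & x <= h50[2]), 0.5 - 0.02)
})
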