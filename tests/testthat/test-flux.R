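# Compositional closure and flux computation.

test_that("composition closure follows the printed stoichiometry", {
  expect_equal(unlist(composition_closure(0, 0)[1, 1:3], use.names = FALSE),
               c(0, 0, 100))
  # 100.09 * 1.2 / 12.01, by hand
  cc <- composition_closure(0, 1.2)
  expect_equal(cc$carbonates, 100.09 * 1.2 / 12.01, tolerance = 1e-12)
  expect_equal(cc$carbonates, 10.0008, tolerance = 1e-4)
  # TIC = 12.01 alone exceeds 100% carbonate: warning + clipped flag
  expect_warning(cc2 <- composition_closure(0, 12.01), "clipped")
  expect_true(cc2$clipped)
  expect_equal(cc2$overshoot, 0.09, tolerance = 1e-9)
  expect_error(composition_closure(-1, 0), class = "limnoflux_parameter_error")
  # conservation whenever no clipping occurred
  set.seed(4)
  toc <- runif(200, 0, 10); tic <- runif(200, 0, 5)
  cc3 <- composition_closure(toc, tic)
  ok <- !cc3$clipped
  expect_lt(max(abs(cc3$carbonates[ok] + cc3$organic_matter[ok] +
                      cc3$silicates[ok] - 100)), 1e-9)
})

test_that("fluxes reproduce hand arithmetic on a controlled ensemble", {
  ens <- linear_ensemble(acc = 10)           # SR = 0.1 cm/yr everywhere
  rec <- data.frame(depth = c(20, 40), TOC = c(2, 0), TIC = c(1, 0),
                    density = c(0.5, 0.5))
  fe <- compute_fluxes(rec, ens)
  expect_equal(fe$toc_flux[, 1], rep(10, 5))    # 0.5*0.1*0.02*1e4
  expect_equal(fe$l_flux[, 1], rep(485, 5))     # 0.5*0.1*0.97*1e4
  expect_equal(fe$toc_flux[, 2], rep(0, 5))     # TOC = 0
  rec2 <- data.frame(depth = 20, TOC = 100, TIC = 0, density = 1)
  expect_equal(compute_fluxes(rec2, ens)$l_flux[, 1], rep(0, 5))
})

test_that("compute_fluxes matches the brute-force oracle to 1e-12", {
  set.seed(8)
  ens <- fit_age_model(
    simulate_dates(const_chron(8, n_sections = 12, thickness = 5),
                   c(10, 30, 55), 5, "calendar", seed = 2),
    settings = age_model_settings(acc_mean = 8, n_iter = 800, burn_in = 200,
                                  n_members = 50),
    seed = 3, core_depth = 60)
  depth <- sort(runif(20, 1, 59))
  TOC <- runif(20, 0, 10); TIC <- runif(20, 0, 5); dens <- runif(20, 0.2, 1.5)
  fe <- compute_fluxes(data.frame(depth = depth, TOC = TOC, TIC = TIC,
                                  density = dens), ens)
  bf <- brute_force_fluxes(depth, TOC, TIC, dens, ens)
  expect_lt(max(abs(fe$toc_flux - bf$toc) / pmax(abs(bf$toc), 1e-12)), 1e-12)
  expect_lt(max(abs(fe$l_flux - bf$l) / pmax(abs(bf$l), 1e-12)), 1e-12)
})

test_that("missing density is a data error unless a fallback is given", {
  ens <- linear_ensemble()
  rec <- data.frame(depth = c(10, 20), TOC = c(1, 1), TIC = c(0, 0),
                    density = c(0.5, NA))
  expect_error(compute_fluxes(rec, ens), class = "limnoflux_data_error")
  fe <- compute_fluxes(rec, ens, density_fallback = 0.4)
  expect_equal(fe$toc_flux[1, 2], 0.4 * 0.1 * 0.01 * 1e4)
})

test_that("increasing SR scales both fluxes proportionally", {
  ens <- linear_ensemble(acc = 10)
  ens_fast <- linear_ensemble(acc = 5)   # SR doubled
  rec <- data.frame(depth = c(15, 45), TOC = c(3, 4), TIC = c(1, 2),
                    density = 0.6)
  f1 <- compute_fluxes(rec, ens)
  f2 <- compute_fluxes(rec, ens_fast)
  expect_equal(f2$toc_flux, 2 * f1$toc_flux, tolerance = 1e-12)
  expect_equal(f2$l_flux, 2 * f1$l_flux, tolerance = 1e-12)
})

test_that("trap fluxes follow mass / (area x time) with closure shares", {
  tf <- trap_flux(10, 0.01, 1, TOC = 10, TIC = 0)
  expect_equal(tf$total, 1000)
  expect_equal(tf$toc_flux, 100)
  expect_equal(tf$lithogenic_flux, 900)
  expect_equal(trap_flux(5, 0.01, 1, TOC = 60, TIC = 40)$lithogenic_flux, 0)
  tf2 <- trap_flux(10, 0.01, 2, TOC = 10, TIC = 0)
  expect_equal(unlist(tf2), unlist(tf) / 2)
  expect_error(trap_flux(10, 0.01, 0, 10), class = "limnoflux_parameter_error")
})

test_that("flux binning averages within bins and flags occupancy", {
  ens <- linear_ensemble(acc = 10, n_members = 1)
  rec <- data.frame(depth = c(5, 15, 25), TOC = c(2, 4, 6), TIC = 0,
                    density = 0.5)
  fe <- compute_fluxes(rec, ens)
  # ages CE: 2015 - c(50,150,250) = 1965, 1865, 1765; bin width 100
  b <- bin_flux_ensemble(fe, 100, 1700, 2000)
  expect_equal(b$occupancy[1, ], c(1L, 1L, 1L))
  expect_equal(b$values[1, 3], fe$toc_flux[1, 1])
  # two samples in one bin -> arithmetic mean
  b2 <- bin_flux_ensemble(fe, 200, 1700, 2100)
  in_bin <- b2$occupancy[1, ] == 2L
  expect_true(any(in_bin))
  expect_equal(b2$values[1, which(in_bin)],
               mean(fe$toc_flux[1, c(2, 3)]))
  expect_error(bin_flux_ensemble(fe, 50, 100, 500),
               class = "limnoflux_data_error")
  s <- flux_band_summary(b)
  expect_named(s, c("bin_centre", "median", "q25", "q75", "q2.5", "q97.5"))
})

test_that("core-top flux averages the first centimetre", {
  ens <- linear_ensemble(acc = 10)
  rec <- data.frame(depth = c(0.4, 0.9, 5), TOC = c(2, 4, 8), TIC = 0,
                    density = 0.5)
  fe <- compute_fluxes(rec, ens)
  ct <- core_top_flux(fe)
  expect_equal(ct$toc_flux, mean(fe$toc_flux[1, 1:2]))
})
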