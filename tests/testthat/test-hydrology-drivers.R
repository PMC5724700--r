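test_that("midsection discharge integrates velocity times depth", {
  # Rectangular channel 4 m wide, 0.5 m deep, uniform 0.25 m/s.
  st <- seq(0, 4, by = 0.25)
  q <- transect_discharge(st, rep(0.5, length(st)), rep(0.25, length(st)))
  expect_equal(q, 0.5)

  expect_equal(transect_discharge(st, rep(0.5, length(st)),
                                  rep(0, length(st))), 0)

  # Triangular depth with linear velocity vs the closed-form integral.
  width <- 4
  st2 <- seq(0, width, by = 0.25)
  depth <- 0.6 * (1 - abs(st2 - width / 2) / (width / 2))
  vel <- 0.1 + 0.05 * depth
  exact <- stats::integrate(function(x) {
    d <- 0.6 * (1 - abs(x - width / 2) / (width / 2))
    (0.1 + 0.05 * d) * d
  }, 0, width)$value
  expect_rel_equal(transect_discharge(st2, depth, vel), exact, 0.02)

  # Additivity over lateral segments.
  left <- transect_discharge(st2[st2 <= 2], depth[st2 <= 2], vel[st2 <= 2])
  right <- transect_discharge(st2[st2 >= 2], depth[st2 >= 2], vel[st2 >= 2])
  expect_equal(left + right, transect_discharge(st2, depth, vel),
               tolerance = 1e-10)

  expect_error(transect_discharge(1, 1, 1), "2 stations")
  expect_error(transect_discharge(c(1, 1), c(1, 1), c(1, 1)), "increasing")
})

test_that("smoothed-minima separation respects recession and capping", {
  # Pure recession: base flow tracks discharge, BFR ~ 1 (the linear
  # chord between block minima sits marginally below the convex curve).
  q <- 2 * exp(-0.03 * (0:39))
  b <- baseflow_separate(q)
  expect_true(all(b <= q + 1e-12))
  expect_gt(bfr(q, b, 9, 40), 0.995)

  # Storm on a constant base: separated base within 10% of truth.
  hg <- gen_hydrograph(hydrograph_spec(n_days = 40, baseflow_level = 0.3,
                                       storm_times = 20,
                                       storm_magnitudes = 1,
                                       storm_recharge = 0, seed = 9))
  sep <- baseflow_separate(hg$q)
  win <- 16:24
  expect_rel_equal(mean(sep[win]), mean(hg$baseflow_true[win]), 0.10)

  # Capping invariant across random hydrographs.
  for (seed in 1:5) {
    hgr <- gen_hydrograph(hydrograph_spec(n_days = 45,
                                          storm_times = c(10, 25, 33),
                                          storm_magnitudes = 0.8,
                                          noise_cv = 0.1, seed = seed))
    expect_true(all(baseflow_separate(hgr$q) <= hgr$q + 1e-12))
  }

  expect_error(baseflow_separate(rep(1, 10)), "at least")
})

test_that("windowed BFR is the equally weighted daily-ratio mean", {
  q <- c(rep(1, 20), rep(2, 10))
  base <- rep(1, 30)
  expect_equal(bfr(q, base, 9, 20), 1)
  expect_equal(bfr(q, base, 10, 30), mean(base[21:30] / q[21:30]))
  expect_error(bfr(q, base, 31, 30), "window")

  # Generated sites ordered by base-flow fraction keep their BFR order.
  high <- gen_hydrograph(hydrograph_spec(n_days = 30, baseflow_level = 1,
                                         storm_times = 26,
                                         storm_magnitudes = 0.1, seed = 3))
  low <- gen_hydrograph(hydrograph_spec(n_days = 30, baseflow_level = 0.2,
                                        storm_times = 26,
                                        storm_magnitudes = 1.5, seed = 3))
  expect_gt(bfr(high$q, high$baseflow_true, 9, 30),
            bfr(low$q, low$baseflow_true, 9, 30))
})

test_that("window scan finds the construction window and stays in [0,1]", {
  ens <- gen_driver_ensemble(n_sites = 24, seed = 11, a = 0)
  sc <- window_scan(ens$points$nem, ens$hydrographs, ens$points$end_day,
                    use_truth = TRUE)
  expect_true(all(sc$r_squared >= 0 & sc$r_squared <= 1))
  expect_lte(abs(attr(sc, "best_window") - 9), 2)

  # NEM independent of hydrology: flat, low profile.
  set.seed(12)
  nem_null <- rnorm(24, 0, 10)
  sc0 <- window_scan(nem_null, ens$hydrographs, ens$points$end_day,
                     use_truth = TRUE)
  expect_lt(max(sc0$r_squared), 0.4)
})

test_that("NEM ~ light regression matches the tabulated points", {
  dp <- driver_points()
  expect_equal(nrow(dp), 12)
  f <- fit_nem_light(dp$par_total, dp$nem)
  expect_lt(abs(f$r_squared - 0.67), 0.01)
  expect_gte(f$zero_crossing, 12)
  expect_equal(f$slope, 4.6, tolerance = 0.05)

  # Collinear points: perfect fit.
  fc <- fit_nem_light(1:5, 2 * (1:5) - 3)
  expect_equal(fc$r_squared, 1)
  expect_equal(fc$zero_crossing, 1.5)

  expect_error(fit_nem_light(rep(1, 5), rnorm(5)), "degenerate")
  expect_error(fit_nem_light(1:2, 1:2), "3 points")
})

test_that("NEM ~ BFR regression behaves like plain OLS", {
  ens <- gen_driver_ensemble(n_sites = 24, seed = 13, a = 0)
  f <- fit_nem_bfr(ens$points$bfr, ens$points$nem)
  se <- stats::coef(summary(f$fit))[2, "Std. Error"]
  expect_lt(abs(f$slope - ens$truth$b), 2 * se)

  # Noise-free linear ensemble: R^2 = 1.
  x <- seq(0.3, 1, length.out = 8)
  expect_equal(fit_nem_bfr(x, 50 * x - 30)$r_squared, 1)

  expect_error(fit_nem_bfr(rep(0.5, 6), rnorm(6)), "degenerate")
})

test_that("combined model nests and dominates the single drivers", {
  dp <- driver_points()
  # BFR stand-ins spanning the reported reach ranges, labelled by site.
  bfr_vals <- c(CL = 0.65, CW = 0.93, GN = 0.78)[dp$site]
  cm <- combined_model(dp$par_total, bfr_vals, dp$nem)
  f_light <- fit_nem_light(dp$par_total, dp$nem)
  f_bfr <- fit_nem_bfr(bfr_vals, dp$nem)
  expect_gte(cm$r_squared, f_light$r_squared)
  expect_gte(cm$r_squared, f_bfr$r_squared)
  expect_gte(cm$r_squared, 0.67)

  # b = 0 truth: combined collapses onto the light-only fit.
  ens0 <- gen_driver_ensemble(n_sites = 24, seed = 14, b = 0, noise_sd = 0)
  cm0 <- combined_model(ens0$points$par_total, ens0$points$bfr,
                        ens0$points$nem)
  expect_equal(unname(cm0$coefficients["b"]), 0, tolerance = 1e-8)
  expect_equal(unname(cm0$coefficients["a"]), ens0$truth$a,
               tolerance = 1e-8)

  # Both drivers active and noisy: both coefficients significant.
  ens2 <- gen_driver_ensemble(n_sites = 24, seed = 15, noise_sd = 10)
  cm2 <- combined_model(ens2$points$par_total, ens2$points$bfr,
                        ens2$points$nem)
  ct <- stats::coef(summary(cm2$fit))
  expect_lt(ct["par_total", "Pr(>|t|)"], 0.05)
  expect_lt(ct["bfr_values", "Pr(>|t|)"], 0.05)

  expect_error(combined_model(1:6, 2 * (1:6), rnorm(6)), "rank-deficient")
})
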