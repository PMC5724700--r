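test_that("quality filter interpolates failing samples", {
  n <- 100
  o2 <- c(rep(1, 49), 99, rep(3, 50))  # failing sample between 1 and 3
  bc <- rep(80, n); bc[50] <- 30
  s <- hf8(u = seq_len(n), o2 = o2, beam_corr = bc)
  out <- quality_filter(s)
  expect_equal(out$o2[50], 2)          # linear interpolation
  expect_equal(attr(out, "gap_fraction"), 0.01)

  clean <- quality_filter(hf8(u = 1:10))
  expect_equal(attr(clean, "gap_fraction"), 0)
  expect_equal(clean$u, as.numeric(1:10))

  all_bad <- hf8(u = 1:10, beam_corr = rep(10, 10))
  expect_error(quality_filter(all_bad), "gap fraction")
})

test_that("filtered synthetic series recovers the clean-series flux", {
  clean <- quick_turbulence(true_flux = -5, duration = 3600,
                            qc_fail_rate = 0)
  dirty <- quick_turbulence(true_flux = -5, duration = 3600,
                            qc_fail_rate = 0.005)
  fx <- function(g) {
    s <- quality_filter(g$series)
    fl <- detrend_fluctuations(s)
    compute_flux(fl$w_p, fl$c_p, fl$window_id)$flux
  }
  expect_rel_equal(fx(dirty), fx(clean), 0.02)
})

test_that("block averaging preserves means and divides length", {
  n <- 64 * 30
  s <- hf_series((seq_len(n) - 1) / 64, u = rep(0.2, n), v = rep(0, n),
                 w = rep(c(1, -1), n / 2), o2 = rep(300, n),
                 sample_rate = 64)
  out <- block_average(s, 8)
  expect_equal(nrow(out), n / 8)
  expect_equal(sample_rate(out), 8)
  expect_true(all(out$w == 0))       # alternating +/-1 averages to 0
  expect_true(all(out$u == 0.2))     # constants unchanged
  expect_error(block_average(s, 7), "divide")
})

test_that("flux survives 64 Hz to 8 Hz averaging", {
  g <- gen_turbulence(turbulence_spec(sample_rate = 64, duration = 1800,
                                      true_flux = -5, timescale = 1,
                                      seed = 31))
  fx_at <- function(s) {
    fl <- detrend_fluctuations(s)
    compute_flux(fl$w_p, fl$c_p, fl$window_id)$flux
  }
  f64 <- fx_at(g$series)
  f8 <- fx_at(block_average(g$series, 8))
  expect_rel_equal(f8, f64, 0.05)
})

test_that("phase-space despiking flags spikes, not turbulence", {
  # False-positive rate on plain Gaussian noise at n = 1e5.
  set.seed(11)
  x <- rnorm(1e5)
  d <- despike_phase_space(x)
  expect_lte(attr(d, "n_spikes") / 1e5, 0.001)

  # A single 10-sigma spike is removed and replaced near its neighbors.
  set.seed(12)
  y <- rnorm(5000)
  y[2500] <- y[2500] + 10
  d2 <- despike_phase_space(y)
  expect_lt(abs(d2[2500]), 4)
  expect_gte(attr(d2, "n_spikes"), 1)

  # Constant series: nothing to flag.
  d3 <- despike_phase_space(rep(2, 100))
  expect_equal(attr(d3, "n_spikes"), 0)

  expect_error(despike_phase_space(c(1, NA, 3)), "finite")
})

test_that("double rotation zeroes mean v/w and preserves speed", {
  g <- quick_turbulence(true_flux = -5, duration = 1800, tilt_deg = 10)
  rot <- double_rotation(g$series)
  expect_lt(abs(mean(rot$v)), 1e-10)
  expect_lt(abs(mean(rot$w)), 1e-10)

  sp_before <- sqrt(g$series$u^2 + g$series$v^2 + g$series$w^2)
  sp_after <- sqrt(rot$u^2 + rot$v^2 + rot$w^2)
  expect_lt(max(abs(sp_after - sp_before) / sp_before), 1e-12)

  # Known 10-degree pitch tilt is recovered and the flux restored.
  expect_equal(unname(attr(rot, "angles")["pitch"]) * 180 / pi, 10,
               tolerance = 0.05)
  g0 <- quick_turbulence(true_flux = -5, duration = 1800, tilt_deg = 0)
  fx <- function(s) {
    fl <- detrend_fluctuations(s)
    compute_flux(fl$w_p, fl$c_p, fl$window_id)$flux
  }
  expect_rel_equal(fx(double_rotation(g$series)), fx(g0$series), 0.02)

  # Pure vertical offset is absorbed into the pitch angle.
  s <- g0$series
  s$w <- s$w + 0.01
  expect_lt(abs(mean(double_rotation(s)$w)), 1e-12)

  still <- hf8(u = rep(0, 100))
  expect_error(double_rotation(still), "zero mean")
})

test_that("linear detrending leaves zero-mean in-window fluctuations", {
  n <- 8 * 900
  tt <- (seq_len(n) - 1) / 8
  ramp <- hf8(u = 0.2 + 0.001 * tt, o2 = 300 + 0.01 * tt)
  fl <- detrend_fluctuations(ramp, window = 300)
  expect_lt(max(abs(fl$u_p)), 1e-9)   # pure ramp: all-zero residuals
  expect_lt(max(abs(fl$c_p)), 1e-9)
  for (j in unique(fl$window_id)) {
    expect_lt(abs(mean(fl$c_p[fl$window_id == j])), 1e-10)
  }

  # Ramp + fast sine: the sine survives detrending almost unchanged.
  sine <- sin(2 * pi * tt / 10)
  s2 <- hf8(u = rep(0.2, n), o2 = 300 + 0.01 * tt + sine)
  fl2 <- detrend_fluctuations(s2, window = 300)
  expect_rel_equal(stats::sd(fl2$c_p), stats::sd(sine[seq_along(fl2$c_p)]),
                   0.01)
  expect_gt(stats::cor(fl2$c_p, sine[seq_along(fl2$c_p)]), 0.999)

  expect_error(detrend_fluctuations(hf8(u = 1:10), window = 300),
               "shorter")
})

test_that("time-shift correction recovers the sensor lag", {
  g <- quick_turbulence(true_flux = -5, duration = 3 * 3600,
                        sensor_lag = 0.5, seed = 21)
  fl <- detrend_fluctuations(g$series)
  ts <- time_shift_correct(fl$w_p, fl$c_p, fl$sample_rate)
  expect_equal(ts$lag_s, 0.5)
  expect_equal(ts$lag_samples, 4L)
  fx <- compute_flux(fl$w_p, ts$c_p, fl$window_id)
  expect_rel_equal(fx$flux, -5, 0.05)

  # Unlagged pair: lag 0, flux untouched.
  g0 <- quick_turbulence(true_flux = -5, duration = 3600, seed = 22)
  fl0 <- detrend_fluctuations(g0$series)
  ts0 <- time_shift_correct(fl0$w_p, fl0$c_p, fl0$sample_rate)
  expect_equal(ts0$lag_s, 0)
  expect_identical(ts0$c_p, fl0$c_p)

  # White noise: no lag-fishing bias beyond sampling error.
  set.seed(23)
  wn <- rnorm(8 * 3600); cn <- rnorm(8 * 3600)
  tsn <- time_shift_correct(wn, cn, 8)
  id <- rep(seq_len(8), each = 8 * 450)
  fxn <- compute_flux(wn, tsn$c_p, id)
  expect_lt(abs(fxn$flux), 3 * fxn$se)

  expect_warning(time_shift_correct(rep(0, 100), rnorm(100), 8),
                 "degenerate")
})

test_that("covariance flux follows the unit chain exactly", {
  # w' = 0.001 C', var(C') = 4 => flux = 0.004 * 3600 = 14.4.
  set.seed(31)
  c_p <- rnorm(20000)
  c_p <- (c_p - mean(c_p)) / sqrt(mean((c_p - mean(c_p))^2)) * 2
  w_p <- 0.001 * c_p
  fx <- compute_flux(w_p, c_p, rep(1L, length(c_p)))
  expect_equal(fx$flux, 0.001 * mean(c_p^2) * 3600)
  expect_equal(fx$flux, 14.4, tolerance = 1e-6)
  expect_true(is.na(fx$se))  # single window has no SE

  # Independent noise: no spurious flux.
  set.seed(32)
  fx0 <- compute_flux(rnorm(48000), rnorm(48000),
                      rep(1:12, each = 4000))
  expect_lt(abs(fx0$flux), 2 * fx0$se)
})

test_that("friction velocity, roughness and drag follow the wall law", {
  set.seed(41)
  w <- rnorm(40000)
  u <- -1e-4 * w + rnorm(40000, sd = 0.002)  # cov(u,w) = -1e-4
  us <- friction_velocity(u, w)
  expect_rel_equal(us$u_star, 0.01, 0.05)

  # Uncorrelated: u* ~ 0 (and never negative).
  us0 <- friction_velocity(rnorm(10000, sd = 0.01),
                           rnorm(10000, sd = 0.01))
  expect_lt(us0$u_star, 2e-3)
  expect_gte(us0$u_star, 0)

  z0 <- roughness_z0(0.15, 0.20, 0.0115)
  expect_equal(z0, 0.15 * exp(-0.41 * 0.20 / 0.0115))
  expect_equal(z0, 1.2e-4, tolerance = 0.01)
  # Algebraic inverse: U reconstructed from (u*/kappa) ln(h/z0).
  expect_equal((0.0115 / 0.41) * log(0.15 / z0), 0.20, tolerance = 1e-12)
  # Limit U/u* -> 0: z0 -> h.
  expect_equal(roughness_z0(0.15, 1e-9, 1), 0.15, tolerance = 1e-9)
  expect_error(roughness_z0(0.15, 0.2, 0), "u_star")

  expect_equal(drag_coefficient(1, 0.0574), 0.0033, tolerance = 0.005)
  expect_equal(drag_coefficient(0.5, 0.5), 1)
  expect_equal(drag_coefficient(0.5, 0), 0)
})

test_that("storage flux reduces to dC/dt times height", {
  # Linear ramp a*t: constant a*h, exact.
  t_h <- seq(0, 3 - 1 / 480, by = 1 / 480)
  o2 <- 250 + 41.8 * t_h
  st <- storage_flux(o2, t_h, h = 0.15)
  expect_equal(st$dcdt, rep(41.8, nrow(st)))
  expect_equal(max(st$f_storage), 6.27)

  # Constant oxygen: zero storage.
  st0 <- storage_flux(rep(300, length(t_h)), t_h, h = 0.15)
  expect_equal(nrow(st0), 3)
  expect_true(all(st0$f_storage == 0))

  # Too short: empty result.
  expect_equal(nrow(storage_flux(rep(300, 10), seq(0, 0.5, length.out = 10),
                                 0.15)), 0)

  expect_equal(benthic_flux(-4, 1), -3)
  expect_equal(benthic_flux(2.5, 0), 2.5)
})

test_that("footprint scales with height and roughness as expected", {
  f1 <- footprint(0.15, 1e-3)
  expect_gt(footprint(0.30, 1e-3)$length, f1$length)   # taller -> longer
  expect_gt(f1$length, footprint(0.15, 5e-3)$length)   # rougher -> shorter
  expect_equal(f1$area, f1$length * f1$width)

  # Field-case envelope: heights 10-19 cm, z0 0.4-1.6 mm.
  for (h in c(0.10, 0.15, 0.19)) {
    for (z0 in c(4e-4, 1e-3, 1.6e-3)) {
      fp <- footprint(h, z0)
      expect_gt(fp$length, 22); expect_lt(fp$length, 181)
      expect_gt(fp$width, 0.5); expect_lt(fp$width, 1.5)
    }
  }
  expect_error(footprint(0.15, 0.2), "z0")
})

test_that("hourly binning averages windows and flags sparse hours", {
  h <- hourly_bin(rep(2, 12), seq(0.04, 0.96, length.out = 12))
  expect_equal(h$flux, 2)
  expect_equal(h$se, 0)
  expect_false(h$flagged)

  h2 <- hourly_bin(rep(c(1, 3), 6), seq(0.04, 0.96, length.out = 12))
  expect_equal(h2$flux, 2)

  h3 <- hourly_bin(c(1, 1, 1), c(0.1, 0.2, 1.5))
  expect_true(h3$flagged[h3$hour == 1])
})

test_that("pipeline recovers truth end-to-end with all artefacts on", {
  spec <- turbulence_spec(true_flux = -5, duration = 3 * 3600,
                          sensor_lag = 0.5, spike_rate = 0.005,
                          qc_fail_rate = 0.005, tilt_deg = 5,
                          storage_slope = 0, seed = 42)
  g <- gen_turbulence(spec)
  res <- aec_pipeline(g$series, h = 0.15)
  expect_rel_equal(res$flux, -5, 0.10)
  expect_equal(res$lag_s, 0.5)
  expect_rel_equal(res$u_star, 0.01, 0.10)
  expect_equal(res$steps[1], "quality_filter")

  # Storage-trend case: EC flux biased, corrected flux near benthic truth.
  g2 <- gen_turbulence(turbulence_spec(true_flux = -4,
                                       storage_slope = 1 / 0.15,
                                       duration = 3 * 3600, seed = 7))
  res2 <- aec_pipeline(g2$series, h = 0.15)
  expect_lt(abs(res2$f_ec - (-4)), 0.4)
  expect_lt(abs(res2$flux - (-3)), 0.4)
})

test_that("hf_series round-trips through delimited text", {
  g <- quick_turbulence(duration = 60)
  path <- withr::local_tempfile(fileext = ".csv")
  write_hf_series(g$series, path)
  back <- read_hf_series(path)
  expect_equal(sample_rate(back), 8)
  expect_equal(back$w, g$series$w, tolerance = 1e-12)
  expect_equal(back$o2, g$series$o2, tolerance = 1e-12)
})
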