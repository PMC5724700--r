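#' Specification for a synthetic turbulence record
#'
#' Bundles the ground-truth parameters for [gen_turbulence()]: a
#' stationary turbulent flow with prescribed benthic oxygen flux,
#' friction velocity and mean flow, plus the instrument artefacts the
#' AEC processing chain must undo (sensor lag, spikes, quality-channel
#' dropouts, measurement noise, a diel storage trend on oxygen).
#'
#' @param sample_rate sampling frequency (Hz), one of 8/16/32/64.
#' @param duration record length (s).
#' @param U mean longitudinal flow (m/s).
#' @param u_star friction velocity (m/s); imposes `-mean(u'w') = u_star^2`.
#' @param true_flux benthic oxygen flux carried by `cov(w', C')`
#'   (mmol O2 m^-2 h^-1; positive = release from the bed).
#' @param mean_o2 mean oxygen concentration (umol/L).
#' @param storage_slope linear oxygen trend dC/dt (umol L^-1 h^-1)
#'   emulating water-column storage.
#' @param spike_rate fraction of samples replaced by isolated 5-10 sigma
#'   excursions; must be below 0.05.
#' @param noise_sd_velocity,noise_sd_o2 white instrument noise (m/s,
#'   umol/L).
#' @param sensor_lag delay of the oxygen channel behind the velocity
#'   sampling volume (s).
#' @param qc_fail_rate fraction of samples whose beam correlation / SNR
#'   are set below the default quality thresholds.
#' @param tilt_deg instrument pitch tilt applied to (u, w) after
#'   construction, for testing double rotation.
#' @param timescale integral timescale of the AR(1) turbulence (s).
#' @param sigma_w standard deviation of vertical velocity fluctuations
#'   (m/s); default scales with `u_star`.
#' @param seed RNG seed.
#'
#' @return A list of class `turbulence_spec`.
#' @export
turbulence_spec <- function(sample_rate = 8, duration = 3 * 3600,
                            U = 0.2, u_star = 0.01, true_flux = -5,
                            mean_o2 = 300, storage_slope = 0,
                            spike_rate = 0, noise_sd_velocity = 0.002,
                            noise_sd_o2 = 0.2, sensor_lag = 0,
                            qc_fail_rate = 0, tilt_deg = 0,
                            timescale = 1, sigma_w = NULL, seed = 1) {
  stop_if_not_positive(sample_rate, "sample_rate")
  stop_if_not_positive(duration, "duration")
  if (spike_rate < 0 || spike_rate >= 0.05) {
    stop("`spike_rate` must lie in [0, 0.05)", call. = FALSE)
  }
  if (sensor_lag < 0) stop("`sensor_lag` must be >= 0", call. = FALSE)
  structure(list(sample_rate = sample_rate, duration = duration, U = U,
                 u_star = u_star, true_flux = true_flux,
                 mean_o2 = mean_o2, storage_slope = storage_slope,
                 spike_rate = spike_rate,
                 noise_sd_velocity = noise_sd_velocity,
                 noise_sd_o2 = noise_sd_o2, sensor_lag = sensor_lag,
                 qc_fail_rate = qc_fail_rate, tilt_deg = tilt_deg,
                 timescale = timescale,
                 sigma_w = sigma_w %||% max(1.2 * u_star, 1e-4),
                 seed = seed),
            class = "turbulence_spec")
}

#' Generate a synthetic AEC turbulence record with known truth
#'
#' Fluctuations are built as linear combinations of independent
#' unit-variance AR(1) processes so that the population covariances
#' exactly match the requested friction velocity (`-mean(u'w') =
#' u_star^2`) and oxygen flux (`cov(w', C') = true_flux / 3600` with C'
#' in mmol/m^3 and w' in m/s). Sample covariances then agree within
#' Monte-Carlo error shrinking as 1/sqrt(n). On top of the clean signal
#' the generator applies, in order: the linear storage trend, sensor
#' lag (oxygen delayed by whole samples), white noise, isolated spikes
#' and quality-channel dropouts, and finally an optional pitch tilt.
#'
#' @param spec a [turbulence_spec()].
#' @return A list with elements `series` (an [hf_series()]) and `truth`
#'   (the imposed flux, friction velocity, lag and trend).
#' @export
gen_turbulence <- function(spec) {
  stopifnot(inherits(spec, "turbulence_spec"))
  with_seed(spec$seed, {
    rate <- spec$sample_rate
    n <- round(rate * spec$duration)
    t <- (seq_len(n) - 1L) / rate

    e_w <- ar1_series(n, rate, spec$timescale)
    e_u <- ar1_series(n, rate, spec$timescale)
    e_c <- ar1_series(n, rate, spec$timescale)

    sigma_w <- spec$sigma_w
    w_p <- sigma_w * e_w

    # u' carries the Reynolds stress: cov(u', w') = -u_star^2.
    c_uw <- -spec$u_star^2
    sigma_u <- max(2.5 * spec$u_star, 1e-4)
    a_u <- c_uw / sigma_w
    resid_u <- sigma_u^2 - a_u^2
    if (resid_u < 0) stop("u_star too large for sigma_u", call. = FALSE)
    u_p <- a_u * e_w + sqrt(resid_u) * e_u

    # C' carries the flux: cov(w', C') = true_flux/3600 (mmol m^-2 s^-1).
    c_wc <- spec$true_flux / 3600
    # Scale sigma_C so the w'-C' correlation stays moderate (~0.4).
    sigma_c <- max(abs(c_wc) / (0.4 * sigma_w), 0.5)
    a_c <- c_wc / sigma_w
    resid_c <- sigma_c^2 - a_c^2
    c_p <- a_c * e_w + sqrt(max(resid_c, 0)) * e_c

    u <- spec$U + u_p
    v <- stats::rnorm(n, 0, spec$noise_sd_velocity)
    w <- w_p
    o2 <- spec$mean_o2 + spec$storage_slope * (t / 3600) + c_p

    # Sensor lag: oxygen channel delayed by whole samples.
    lag_n <- round(spec$sensor_lag * rate)
    if (lag_n > 0) {
      o2 <- c(rep(o2[1L], lag_n), o2[seq_len(n - lag_n)])
    }

    u <- u + stats::rnorm(n, 0, spec$noise_sd_velocity)
    w <- w + stats::rnorm(n, 0, spec$noise_sd_velocity)
    o2 <- o2 + stats::rnorm(n, 0, spec$noise_sd_o2)

    # Isolated spikes of 5-10 sigma, alternating sign.
    if (spec$spike_rate > 0) {
      n_spk <- max(1L, round(spec$spike_rate * n))
      at <- sample(seq(5L, n - 5L), n_spk)
      amp <- stats::runif(n_spk, 5, 10) * sample(c(-1, 1), n_spk, TRUE)
      w[at] <- w[at] + amp * stats::sd(w)
      o2[at] <- o2[at] + amp * stats::sd(c_p)
    }

    beam <- pmin(100, stats::rnorm(n, 85, 5))
    snr <- stats::rnorm(n, 25, 4)
    if (spec$qc_fail_rate > 0) {
      bad <- sample(n, round(spec$qc_fail_rate * n))
      beam[bad] <- stats::runif(length(bad), 10, 45)
    }
    snr <- pmax(snr, 11)
    if (spec$qc_fail_rate > 0) snr[sample(n, round(spec$qc_fail_rate * n / 2))] <- 5

    # Optional pitch tilt about the transverse axis.
    if (spec$tilt_deg != 0) {
      th <- spec$tilt_deg * pi / 180
      u_t <- cos(th) * u - sin(th) * w
      w <- sin(th) * u + cos(th) * w
      u <- u_t
    }

    series <- hf_series(t, u, v, w, o2, beam_corr = beam, snr = snr,
                        sample_rate = rate)
    list(series = series,
         truth = list(flux = spec$true_flux, u_star = spec$u_star,
                      U = spec$U, sensor_lag = spec$sensor_lag,
                      storage_slope = spec$storage_slope,
                      sigma_w = sigma_w, sigma_c = sigma_c))
  })
}
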