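#' Specification of a synthetic incubation campaign
#'
#' Ground truth for [gen_bottles()]: a 24-h bottle incubation with a
#' half-sinusoid photosynthetically active radiation (PAR) cycle and
#' linear oxygen drifts in clear and dark bottles.
#'
#' @param site,season labels.
#' @param depth mean stream depth (m).
#' @param width stream width (m).
#' @param daylight_hours,night_hours duration of day and night (h);
#'   must sum to 24.
#' @param par_peak midday PAR just below the surface
#'   (umol quanta m^-2 s^-1).
#' @param pe_truth optional numeric `c(Pmax, Ek, R)` for benthic
#'   light-response simulations.
#' @param water_day_rate net volumetric rate in clear bottles during
#'   daylight (umol L^-1 h^-1).
#' @param water_night_rate dark-bottle rate, applied throughout
#'   (umol L^-1 h^-1; negative = respiration).
#' @param o2_start initial bottle oxygen (umol/L).
#' @param noise_sd optical-sensor noise (umol/L).
#' @param step_min sampling interval (minutes).
#' @param seed RNG seed.
#' @return A list of class `campaign_spec`.
#' @export
campaign_spec <- function(site = "SYN", season = "spring", depth = 0.4,
                          width = 3, daylight_hours = 15.3,
                          night_hours = 24 - daylight_hours,
                          par_peak = 600, pe_truth = NULL,
                          water_day_rate = 9, water_night_rate = -1,
                          o2_start = 300, noise_sd = 1, step_min = 5,
                          seed = 1) {
  stop_if_not_positive(depth, "depth")
  if (abs(daylight_hours + night_hours - 24) > 1e-9) {
    stop("daylight_hours + night_hours must equal 24", call. = FALSE)
  }
  structure(list(site = site, season = season, depth = depth,
                 width = width, daylight_hours = daylight_hours,
                 night_hours = night_hours, par_peak = par_peak,
                 pe_truth = pe_truth, water_day_rate = water_day_rate,
                 water_night_rate = water_night_rate,
                 o2_start = o2_start, noise_sd = noise_sd,
                 step_min = step_min, seed = seed),
            class = "campaign_spec")
}

#' Half-sinusoid diel PAR cycle
#'
#' PAR rises as a half sine over the daylight span centred on local
#' noon and is zero at night (below the 2 umol quanta m^-2 s^-1
#' night-definition threshold).
#'
#' @param time_h time of day (h, 0-24).
#' @param daylight_hours daylight duration (h).
#' @param par_peak midday maximum (umol quanta m^-2 s^-1).
#' @return PAR values (umol quanta m^-2 s^-1).
#' @export
diel_par <- function(time_h, daylight_hours, par_peak) {
  rise <- 12 - daylight_hours / 2
  x <- (time_h - rise) / daylight_hours
  ifelse(x > 0 & x < 1, par_peak * sin(pi * x), 0)
}

#' Generate a synthetic bottle-incubation set
#'
#' Three clear bottles (surface/mid/bottom) and one dark bottle over
#' 24 h. Clear bottles drift at the daytime rate while PAR exceeds the
#' night threshold and at the dark rate otherwise; the dark bottle
#' drifts at the night rate throughout. Gaussian sensor noise is added
#' to every reading.
#'
#' @param campaign a [campaign_spec()].
#' @return A list with `bottles` (long data frame: `bottle`, `role`,
#'   `position`, `time_h`, `o2`), `par` (data frame `time_h`, `par`)
#'   and `truth`.
#' @export
gen_bottles <- function(campaign) {
  stopifnot(inherits(campaign, "campaign_spec"))
  with_seed(campaign$seed, {
    t_h <- seq(0, 24, by = campaign$step_min / 60)
    par <- diel_par(t_h, campaign$daylight_hours, campaign$par_peak)
    day <- par >= 2

    drift <- function(rate_day, rate_night) {
      inst <- ifelse(day, rate_day, rate_night)
      dt <- c(0, diff(t_h))
      campaign$o2_start + cumsum(inst * dt)
    }

    mk <- function(id, role, position) {
      clean <- if (role == "clear") {
        drift(campaign$water_day_rate, campaign$water_night_rate)
      } else {
        drift(campaign$water_night_rate, campaign$water_night_rate)
      }
      data.frame(bottle = id, role = role, position = position,
                 time_h = t_h,
                 o2 = clean + stats::rnorm(length(t_h), 0, campaign$noise_sd))
    }

    bottles <- rbind(mk("C1", "clear", "surface"),
                     mk("C2", "clear", "mid"),
                     mk("C3", "clear", "bottom"),
                     mk("D1", "dark", "bottom"))
    list(bottles = bottles,
         par = data.frame(time_h = t_h, par = par),
         truth = list(day_rate = campaign$water_day_rate,
                      night_rate = campaign$water_night_rate,
                      daylight_hours = sum(day) * campaign$step_min / 60))
  })
}

#' Specification of a synthetic daily hydrograph
#'
#' @param n_days number of days.
#' @param baseflow_level long-term base-flow discharge (m^3 s^-1).
#' @param baseflow_recession_constant recession rate of base-flow
#'   excursions back toward `baseflow_level` (d^-1).
#' @param storm_times days on which storm pulses peak.
#' @param storm_magnitudes peak storm runoff added to base flow
#'   (m^3 s^-1); recycled to the length of `storm_times`.
#' @param storm_recession_constant fast recession of storm runoff (d^-1).
#' @param storm_recharge fraction of each storm magnitude added to the
#'   base-flow component (slow groundwater recharge).
#' @param noise_cv multiplicative lognormal noise on total discharge.
#' @param seed RNG seed.
#' @return A list of class `hydrograph_spec`.
#' @export
hydrograph_spec <- function(n_days = 60, baseflow_level = 0.2,
                            baseflow_recession_constant = 0.05,
                            storm_times = integer(), storm_magnitudes = 0.5,
                            storm_recession_constant = 1,
                            storm_recharge = 0.1, noise_cv = 0,
                            seed = 1) {
  stop_if_not_positive(n_days, "n_days")
  stop_if_not_positive(baseflow_level, "baseflow_level")
  structure(list(n_days = n_days, baseflow_level = baseflow_level,
                 k_base = baseflow_recession_constant,
                 storm_times = storm_times,
                 storm_magnitudes = rep_len(storm_magnitudes,
                                            length(storm_times)),
                 k_storm = storm_recession_constant,
                 storm_recharge = storm_recharge, noise_cv = noise_cv,
                 seed = seed),
            class = "hydrograph_spec")
}

#' Generate a daily hydrograph with known base-flow component
#'
#' Total discharge is the sum of a slowly varying base flow (storm
#' recharge decaying at the base-flow recession constant toward the
#' base-flow level) and fast-receding storm runoff pulses. Both
#' components are stored, so the true base-flow ratio of any window is
#' computable exactly.
#'
#' @param spec a [hydrograph_spec()].
#' @return A data frame with columns `day`, `q` (total discharge),
#'   `baseflow_true` (m^3 s^-1); base flow never exceeds `q`.
#' @export
gen_hydrograph <- function(spec) {
  stopifnot(inherits(spec, "hydrograph_spec"))
  with_seed(spec$seed, {
    days <- seq_len(spec$n_days)
    base <- rep(spec$baseflow_level, spec$n_days)
    storm <- rep(0, spec$n_days)
    for (i in seq_along(spec$storm_times)) {
      t0 <- spec$storm_times[i]
      mag <- spec$storm_magnitudes[i]
      after <- days >= t0
      storm[after] <- storm[after] +
        mag * exp(-spec$k_storm * (days[after] - t0))
      base[after] <- base[after] +
        spec$storm_recharge * mag * exp(-spec$k_base * (days[after] - t0))
    }
    if (spec$noise_cv > 0) {
      # Shared multiplicative noise keeps baseflow_true <= q.
      f <- exp(stats::rnorm(spec$n_days, 0, spec$noise_cv))
      base <- base * f
      storm <- storm * f
    }
    data.frame(day = days, q = base + storm, baseflow_true = base)
  })
}

#' Generate a driver ensemble with known light/hydrology dependence
#'
#' Builds `n_sites` synthetic site-seasons, each with its own
#' hydrograph (random storms, some near the campaign day), a streambed
#' PAR integral, and net ecosystem metabolism constructed as
#' `NEM = a * PAR + b * BFR9 + c + noise`, where `BFR9` is the true
#' base-flow ratio over the 9-day window ending on the campaign day.
#'
#' @param n_sites number of site-season points (>= 3).
#' @param seed RNG seed.
#' @param a,b,c true PAR slope (mmol m^-2 d^-1 per mol quanta m^-2
#'   d^-1), BFR slope and intercept (mmol m^-2 d^-1).
#' @param noise_sd Gaussian noise on NEM (mmol m^-2 d^-1).
#' @param window_days driver window used to construct NEM (d).
#' @param n_days hydrograph length per site (d).
#' @return A list with `points` (data frame `site`, `par_total`, `bfr`,
#'   `nem`, `end_day`), `hydrographs` (named list of hydrograph data
#'   frames) and `truth`.
#' @export
gen_driver_ensemble <- function(n_sites = 12, seed = 1, a = 4.6,
                                b = 100, c = -90, noise_sd = 10,
                                window_days = 9, n_days = 60) {
  if (n_sites < 3) stop("`n_sites` must be >= 3", call. = FALSE)
  with_seed(seed, {
    end_day <- n_days - 10L
    sites <- sprintf("S%02d", seq_len(n_sites))
    hydros <- list()
    pts <- vector("list", n_sites)
    for (i in seq_len(n_sites)) {
      n_storm <- sample(1:3, 1)
      # Scatter storms across the month before (and just after) the
      # campaign so base-flow ratios decorrelate across window
      # lengths and the driver window is identifiable.
      t_storm <- sort(sample(seq(end_day - 30L, end_day + 2L), n_storm))
      hs <- hydrograph_spec(
        n_days = n_days,
        baseflow_level = stats::runif(1, 0.05, 0.4),
        storm_times = t_storm,
        storm_magnitudes = stats::runif(n_storm, 0.2, 1.5),
        seed = sample.int(1e6, 1))
      hg <- gen_hydrograph(hs)
      hydros[[sites[i]]] <- hg
      bfr9 <- bfr(hg$q, hg$baseflow_true, window_days = window_days,
                  end_day = end_day)
      par_total <- stats::runif(1, 0.3, 29)
      nem <- a * par_total + b * bfr9 + c + stats::rnorm(1, 0, noise_sd)
      pts[[i]] <- data.frame(site = sites[i], par_total = par_total,
                             bfr = bfr9, nem = nem, end_day = end_day)
    }
    list(points = do.call(rbind, pts), hydrographs = hydros,
         truth = list(a = a, b = b, c = c, window_days = window_days))
  })
}
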