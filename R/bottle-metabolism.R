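#' Day/night partition from PAR
#'
#' Night is defined as PAR strictly below the threshold (default
#' 2 umol quanta m^-2 s^-1); a sample exactly at the threshold counts
#' as day.
#'
#' @param par PAR series (umol quanta m^-2 s^-1), non-negative.
#' @param time_h sample times (h); used to report daylight duration.
#' @param threshold night threshold (umol quanta m^-2 s^-1).
#' @return Logical day mask with attributes `daylight_hours` and
#'   `flag` ("all_day"/"all_night" when degenerate, else NA).
#' @export
partition_day_night <- function(par, time_h = NULL, threshold = 2) {
  if (any(par < 0, na.rm = TRUE)) stop("PAR must be >= 0", call. = FALSE)
  day <- par >= threshold
  dl <- if (!is.null(time_h) && length(time_h) > 1) {
    sum(day) * stats::median(diff(time_h))
  } else NA_real_
  flag <- if (all(day)) "all_day" else if (!any(day)) "all_night"
          else NA_character_
  structure(day, daylight_hours = dl, flag = flag)
}

#' Volumetric bottle rate by linear regression
#'
#' Least-squares slope of the oxygen time series over the masked span,
#' in umol L^-1 h^-1; the paper-of-record practice is to accept fits
#' with R^2 > 0.8 and flag weaker ones.
#'
#' @param o2 oxygen series (umol/L).
#' @param time_h times (h).
#' @param mask logical subset to fit (default: all samples).
#' @param min_n minimum samples required.
#' @param r2_min flag threshold for the coefficient of determination.
#' @return A list with `rate` (umol L^-1 h^-1), `r_squared`, `n` and
#'   `flagged` (TRUE when R^2 is below `r2_min` or undefined).
#' @export
fit_bottle_rate <- function(o2, time_h, mask = rep(TRUE, length(o2)),
                            min_n = 5, r2_min = 0.8) {
  o2 <- o2[mask]; time_h <- time_h[mask]
  if (length(o2) < min_n) {
    stop(sprintf("need at least %d samples in masked span", min_n),
         call. = FALSE)
  }
  fit <- stats::lm(o2 ~ time_h)
  rate <- unname(stats::coef(fit)[2])
  tss <- sum((o2 - mean(o2))^2)
  r2 <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else NA_real_
  list(rate = rate, r_squared = r2, n = length(o2),
       flagged = is.na(r2) || r2 < r2_min)
}

#' Fit day and night rates for a bottle set
#'
#' Clear-bottle slopes are fitted over the daylight span and averaged
#' across depth positions (vertical differences are typically not
#' significant); dark-bottle slopes are fitted over day and night
#' separately and averaged with equal weight to give the night rate.
#'
#' @param bottles long data frame with columns `bottle`, `role`
#'   ("clear"/"dark"), `position`, `time_h`, `o2`.
#' @param par data frame with `time_h`, `par` aligned to the bottles.
#' @param threshold night PAR threshold.
#' @return A list with `day_rate`, `night_rate` (umol L^-1 h^-1),
#'   `daylight_hours`, `night_hours`, `per_bottle` (data frame) and
#'   `flagged`.
#' @export
bottle_rates <- function(bottles, par, threshold = 2) {
  stopifnot(all(c("bottle", "role", "time_h", "o2") %in% names(bottles)))
  roles <- unique(bottles$role)
  if (!all(c("clear", "dark") %in% roles)) {
    stop("need at least one clear and one dark bottle", call. = FALSE)
  }
  ids <- unique(bottles$bottle)
  day_of <- function(t) {
    m <- partition_day_night(par$par, par$time_h, threshold)
    as.logical(m)[match(round(t, 6), round(par$time_h, 6))]
  }
  rows <- list()
  for (id in ids) {
    b <- bottles[bottles$bottle == id, ]
    day <- day_of(b$time_h)
    if (b$role[1] == "clear") {
      f <- fit_bottle_rate(b$o2, b$time_h, day)
      rows[[id]] <- data.frame(bottle = id, role = "clear",
                               position = b$position[1], span = "day",
                               rate = f$rate, r_squared = f$r_squared,
                               flagged = f$flagged)
    } else {
      fd <- fit_bottle_rate(b$o2, b$time_h, day)
      fn <- fit_bottle_rate(b$o2, b$time_h, !day)
      rows[[paste0(id, "_d")]] <- data.frame(bottle = id, role = "dark",
        position = b$position[1], span = "day", rate = fd$rate,
        r_squared = fd$r_squared, flagged = fd$flagged)
      rows[[paste0(id, "_n")]] <- data.frame(bottle = id, role = "dark",
        position = b$position[1], span = "night", rate = fn$rate,
        r_squared = fn$r_squared, flagged = fn$flagged)
    }
  }
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  mask <- partition_day_night(par$par, par$time_h, threshold)
  dl <- attr(mask, "daylight_hours")
  list(day_rate = mean(per$rate[per$role == "clear"]),
       night_rate = mean(per$rate[per$role == "dark"]),
       daylight_hours = dl, night_hours = 24 - dl,
       per_bottle = per, flagged = any(per$flagged))
}

#' Areal water-column rates from volumetric incubation rates
#'
#' Converts volumetric rates (umol L^-1 h^-1 = mmol m^-3 h^-1) into
#' areal daily rates (mmol m^-2 d^-1) by multiplying with the mean
#' stream depth:
#' `ER_w = |night| * 24 * depth`;
#' `GPP_w = (day - night) * daylight_hours * depth`, floored at zero;
#' `NEM_w = (day * daylight_hours + night * night_hours) * depth`.
#' When the daytime rate is undetectable (`NA`), NEM_w falls back to
#' the night rate scaled to 24 h. Values below the 0.1 mmol m^-2 d^-1
#' detection floor are stored as 0 and rendered "<0.1" in reports.
#'
#' @param day_rate,night_rate volumetric rates (umol L^-1 h^-1);
#'   `night_rate` is negative for respiration.
#' @param daylight_hours,night_hours day/night durations (h), summing
#'   to 24.
#' @param depth mean stream depth (m).
#' @return A list with `er_w`, `gpp_w`, `nem_w` (mmol m^-2 d^-1) and
#'   `below_detection` (named logical).
#' @export
areal_rates <- function(day_rate, night_rate, daylight_hours,
                        night_hours, depth) {
  stop_if_not_positive(depth, "depth")
  er <- abs(night_rate) * 24 * depth
  if (is.na(day_rate)) {
    gpp <- NA_real_
    nem <- night_rate * 24 * depth
  } else {
    gpp <- max((day_rate - night_rate) * daylight_hours, 0) * depth
    nem <- (day_rate * daylight_hours + night_rate * night_hours) * depth
  }
  floor_det <- function(x) if (!is.na(x) && abs(x) < 0.1) 0 else x
  bd <- c(er_w = !is.na(er) && abs(er) < 0.1,
          gpp_w = !is.na(gpp) && abs(gpp) < 0.1,
          nem_w = !is.na(nem) && abs(nem) < 0.1)
  list(er_w = floor_det(er), gpp_w = floor_det(gpp),
       nem_w = floor_det(nem), below_detection = bd)
}

#' Net rate from endpoint oxygen change
#'
#' For bottles sampled only at the start and end of an incubation
#' (e.g. by Winkler titration), the net volumetric rate is the total
#' concentration change divided by the duration.
#'
#' @param initial,final oxygen concentrations (umol/L).
#' @param duration incubation length (h).
#' @return Net rate (umol L^-1 h^-1).
#' @export
net_24h_change <- function(initial, final, duration) {
  stop_if_not_positive(duration, "duration")
  (final - initial) / duration
}
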