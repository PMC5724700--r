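#' Daily benthic metabolism budget from mean day/night fluxes
#'
#' Scales campaign-mean hourly benthic fluxes (mmol m^-2 h^-1) to
#' daily rates (mmol m^-2 d^-1):
#' `ER = |night| * 24` (respiration assumed light-independent),
#' `GPP = (day - night) * daylight_hours` floored at zero, and
#' `NEM = day * daylight_hours + night * night_hours`, so that
#' `NEM = GPP - ER` holds exactly whenever GPP is not floored.
#'
#' @param day_flux,night_flux mean hourly benthic fluxes
#'   (mmol m^-2 h^-1); positive = oxygen release.
#' @param daylight_h,night_h day/night durations (h), summing to 24.
#' @param site,season optional labels.
#' @return A one-row `metabolism summary` data frame with columns
#'   `site`, `season`, `compartment`, `er`, `gpp`, `nem`,
#'   `daylight_h`, `night_h`.
#' @export
daily_benthic_budget <- function(day_flux, night_flux, daylight_h,
                                 night_h, site = NA_character_,
                                 season = NA_character_) {
  if (abs(daylight_h + night_h - 24) > 1e-9) {
    stop("daylight_h + night_h must equal 24", call. = FALSE)
  }
  if (!is.na(night_flux) && night_flux > 0) {
    warning("positive night flux: apparent nighttime oxygen release")
  }
  er <- abs(night_flux) * 24
  gpp <- max((day_flux - night_flux) * daylight_h, 0)
  nem <- day_flux * daylight_h + night_flux * night_h
  data.frame(site = site, season = season, compartment = "benthic",
             er = er, gpp = gpp, nem = nem,
             daylight_h = daylight_h, night_h = night_h)
}

#' Water-column metabolism summary row
#'
#' Wraps areal water-column rates (e.g. from [areal_rates()]) in the
#' same summary layout as [daily_benthic_budget()].
#'
#' @param er,gpp,nem areal rates (mmol m^-2 d^-1).
#' @param daylight_h,night_h day/night durations (h).
#' @param site,season optional labels.
#' @return A one-row metabolism summary data frame.
#' @export
water_summary <- function(er, gpp, nem, daylight_h = NA_real_,
                          night_h = NA_real_, site = NA_character_,
                          season = NA_character_) {
  data.frame(site = site, season = season, compartment = "water",
             er = er, gpp = gpp, nem = nem,
             daylight_h = daylight_h, night_h = night_h)
}

#' Combine benthic and water-column compartments
#'
#' Element-wise sums of ER, GPP and NEM for matching site/season rows,
#' yielding the whole-stream rates (benthic + water column).
#'
#' @param benthic,water one-row metabolism summary data frames with
#'   matching `site` and `season`.
#' @return A one-row summary with `compartment = "combined"`.
#' @export
combine_compartments <- function(benthic, water) {
  same <- function(a, b) (is.na(a) && is.na(b)) || identical(a, b)
  if (!same(benthic$site, water$site) ||
      !same(benthic$season, water$season)) {
    stop("site/season labels do not match", call. = FALSE)
  }
  na0 <- function(x) if (is.na(x)) 0 else x
  data.frame(site = benthic$site, season = benthic$season,
             compartment = "combined",
             er = na0(benthic$er) + na0(water$er),
             gpp = na0(benthic$gpp) + na0(water$gpp),
             nem = na0(benthic$nem) + na0(water$nem),
             daylight_h = benthic$daylight_h, night_h = benthic$night_h)
}

#' Relative benthic contribution to whole-stream metabolism
#'
#' Percentage share `100 * benthic / combined` for ER, GPP and NEM.
#' Ratios with a zero combined rate are undefined and rendered `NA`;
#' shares above 100% arise when benthic and water-column NEM have
#' opposite signs and are flagged.
#'
#' @param benthic,combined one-row metabolism summaries.
#' @return A list with `er_pct`, `gpp_pct`, `nem_pct` and
#'   `opposite_sign_nem`.
#' @export
relative_contribution <- function(benthic, combined) {
  share <- function(b, tot) {
    if (is.na(tot) || tot == 0) NA_real_ else 100 * b / tot
  }
  water_nem <- combined$nem - benthic$nem
  list(er_pct = share(benthic$er, combined$er),
       gpp_pct = share(benthic$gpp, combined$gpp),
       nem_pct = share(benthic$nem, combined$nem),
       opposite_sign_nem = !is.na(benthic$nem) && !is.na(water_nem) &&
         benthic$nem * water_nem < 0)
}

#' Annual mean from four seasonal summaries
#'
#' The annual daily metabolism is approximated as the arithmetic mean
#' of the four seasonal rates. A missing season aborts unless an
#' explicit substitution is supplied (e.g. re-using the autumn
#' water-column rate for an unsampled winter); substitution is never
#' silent.
#'
#' @param x numeric seasonal values (named by season) or a metabolism
#'   summary data frame with a `season` column and `value_col`.
#' @param substitutions named list mapping a missing season to the
#'   season whose value stands in for it, e.g.
#'   `list(winter = "autumn")`.
#' @param value_col column to average when `x` is a data frame.
#' @return The annual mean.
#' @export
annual_mean <- function(x, substitutions = NULL, value_col = "nem") {
  if (is.data.frame(x)) {
    v <- stats::setNames(x[[value_col]], x$season)
  } else {
    v <- x
  }
  seasons <- c("spring", "summer", "autumn", "winter")
  if (is.null(names(v)) && length(v) == 4L) names(v) <- seasons
  for (s in names(substitutions %||% list())) {
    v[s] <- v[[substitutions[[s]]]]
  }
  missing <- setdiff(seasons, names(v)[!is.na(v)])
  if (length(missing) > 0) {
    stop(sprintf("missing season(s) %s: supply an explicit substitution",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  mean(v[seasons])
}

#' Mean over a period with a short production peak
#'
#' Weights a short-lived peak rate against a background rate over the
#' full period: `(peak_weeks * peak + (total - peak) * background) /
#' total`. Used to extrapolate a ~1-week spring bloom over the whole
#' season.
#'
#' @param peak_value rate during the peak.
#' @param background_value rate for the remainder of the period.
#' @param peak_weeks,total_weeks durations (weeks), with
#'   `0 <= peak_weeks <= total_weeks`.
#' @return The period-mean rate.
#' @export
weighted_period_mean <- function(peak_value, background_value,
                                 peak_weeks, total_weeks) {
  if (total_weeks <= 0) stop("`total_weeks` must be > 0", call. = FALSE)
  if (peak_weeks < 0 || peak_weeks > total_weeks) {
    stop("`peak_weeks` must lie in [0, total_weeks]", call. = FALSE)
  }
  (peak_weeks * peak_value +
     (total_weeks - peak_weeks) * background_value) / total_weeks
}

#' Render a rate with the reporting detection floor
#'
#' Rates below 0.1 mmol m^-2 d^-1 in magnitude print as `"<0.1"`;
#' others are rounded to one decimal.
#'
#' @param x numeric rate (mmol m^-2 d^-1).
#' @return Character rendering.
#' @export
format_rate <- function(x) {
  ifelse(is.na(x), "n.d.",
         ifelse(abs(x) < 0.1, "<0.1", sprintf("%.1f", x)))
}
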