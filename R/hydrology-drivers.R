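#' Cross-sectional discharge by the midsection method
#'
#' Integrates depth x mean-column-velocity across lateral stations:
#' each station is assigned the width from the midpoints to its
#' neighbours (half the adjacent spacing at the end stations), and
#' `Q = sum(v_i * d_i * w_i)`.
#'
#' @param station lateral positions (m), strictly increasing.
#' @param depth water depths (m), `>= 0`.
#' @param velocity depth-averaged velocities (m/s) per station.
#' @return Discharge Q (m^3 s^-1).
#' @export
transect_discharge <- function(station, depth, velocity) {
  n <- length(station)
  if (n < 2) stop("need at least 2 stations", call. = FALSE)
  if (any(diff(station) <= 0)) {
    stop("stations must be strictly increasing", call. = FALSE)
  }
  if (any(depth < 0)) stop("depths must be >= 0", call. = FALSE)
  mid <- (station[-1] + station[-n]) / 2
  left <- c(station[1], mid)
  right <- c(mid, station[n])
  sum(velocity * depth * (right - left))
}

#' Base-flow separation by the UK smoothed-minima procedure
#'
#' Daily discharge is split into non-overlapping 5-day blocks and the
#' minimum of each block located. A block minimum is a turning point
#' when, scaled by the factor 0.9, it does not exceed either
#' neighbouring block minimum. The base-flow line interpolates
#' linearly between turning points (held constant beyond the outermost
#' ones) and is capped at the observed discharge, so the base-flow
#' ratio never exceeds 1.
#'
#' @param q daily discharge series (m^3 s^-1), at least 15 days.
#' @param block_days block length (d).
#' @param turning_factor scaling factor of the turning-point test.
#' @return Base-flow series (m^3 s^-1), same length as `q`.
#' @export
baseflow_separate <- function(q, block_days = 5, turning_factor = 0.9) {
  n <- length(q)
  if (n < 3 * block_days) {
    stop(sprintf("need at least %d days of data", 3 * block_days),
         call. = FALSE)
  }
  n_blk <- floor(n / block_days)
  idx_min <- integer(n_blk)
  for (b in seq_len(n_blk)) {
    span <- ((b - 1) * block_days + 1):(b * block_days)
    idx_min[b] <- span[which.min(q[span])]
  }
  qmin <- q[idx_min]
  turning <- logical(n_blk)
  for (b in 2:(n_blk - 1)) {
    turning[b] <- turning_factor * qmin[b] <= min(qmin[b - 1], qmin[b + 1])
  }
  # End blocks anchor the line so the series is covered.
  turning[c(1, n_blk)] <- TRUE
  tp_day <- idx_min[turning]
  tp_q <- qmin[turning]
  base <- stats::approx(tp_day, tp_q, xout = seq_len(n), rule = 2)$y
  pmin(base, q)
}

#' Base-flow ratio over a window
#'
#' Mean of the daily ratio `baseflow / q` over a window of
#' `window_days` days ending on `end_day` (the window starts before a
#' field campaign and includes it), days weighted equally.
#'
#' @param q daily discharge (m^3 s^-1).
#' @param baseflow daily base flow (m^3 s^-1), e.g. from
#'   [baseflow_separate()] or a generator's stored truth.
#' @param window_days window length (d).
#' @param end_day index of the last day of the window (default: last
#'   day of the series).
#' @return Mean base-flow ratio in `[0, 1]`.
#' @export
bfr <- function(q, baseflow, window_days = 9, end_day = length(q)) {
  stopifnot(length(baseflow) == length(q))
  days <- (end_day - window_days + 1):end_day
  if (min(days) < 1 || max(days) > length(q)) {
    stop("window not fully covered by data", call. = FALSE)
  }
  mean(baseflow[days] / q[days])
}

#' Scan driver-window lengths for the NEM ~ BFR relationship
#'
#' For each candidate window length, recomputes every site's base-flow
#' ratio over that window and the R^2 of the ordinary least-squares
#' regression of NEM on BFR. The window at which R^2 peaks estimates
#' the timescale over which hydrology imprints reach-scale carbon
#' turnover.
#'
#' @param nem net ecosystem metabolism per site (mmol m^-2 d^-1).
#' @param hydrographs list (one per site) of data frames with columns
#'   `q` and either `baseflow` or `baseflow_true`.
#' @param end_days last window day per site (recycled if length 1).
#' @param windows candidate window lengths (d).
#' @param use_truth use the stored `baseflow_true` column instead of
#'   running [baseflow_separate()].
#' @return Data frame with `window` and `r_squared`, plus attribute
#'   `best_window`.
#' @export
window_scan <- function(nem, hydrographs, end_days, windows = 2:30,
                        use_truth = FALSE) {
  n_site <- length(hydrographs)
  if (n_site < 6) stop("need at least 6 points", call. = FALSE)
  stopifnot(length(nem) == n_site)
  end_days <- rep_len(end_days, n_site)
  base <- lapply(hydrographs, function(hg) {
    if (use_truth && "baseflow_true" %in% names(hg)) {
      hg$baseflow_true
    } else if ("baseflow" %in% names(hg)) {
      hg$baseflow
    } else {
      baseflow_separate(hg$q)
    }
  })
  r2 <- vapply(windows, function(w) {
    x <- vapply(seq_len(n_site), function(i) {
      bfr(hydrographs[[i]]$q, base[[i]], w, end_days[i])
    }, numeric(1))
    if (stats::sd(x) == 0) return(0)
    ols_r2(stats::lm(nem ~ x), nem)
  }, numeric(1))
  out <- data.frame(window = windows, r_squared = r2)
  attr(out, "best_window") <- windows[which.max(r2)]
  out
}

#' Linear NEM ~ light regression
#'
#' Ordinary least squares of net ecosystem metabolism on the daily
#' streambed PAR integral. The zero crossing `-intercept/slope` is the
#' light level at which the reach switches from net heterotrophy to
#' net autotrophy.
#'
#' @param par_total daily-integrated streambed PAR
#'   (mol quanta m^-2 d^-1).
#' @param nem whole-stream NEM (mmol m^-2 d^-1).
#' @return A list with `slope`, `intercept`, `r_squared`,
#'   `zero_crossing` and the `lm` fit.
#' @export
fit_nem_light <- function(par_total, nem) {
  if (length(par_total) < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(par_total) == 0) {
    stop("degenerate predictor: constant PAR", call. = FALSE)
  }
  f <- stats::lm(nem ~ par_total)
  cf <- stats::coef(f)
  list(slope = unname(cf[2]), intercept = unname(cf[1]),
       r_squared = ols_r2(f, nem),
       zero_crossing = unname(-cf[1] / cf[2]), fit = f)
}

#' Linear NEM ~ base-flow-ratio regression
#'
#' @param bfr_values windowed base-flow ratios per site-season.
#' @param nem whole-stream NEM (mmol m^-2 d^-1).
#' @return A list with `slope`, `intercept`, `r_squared` and the `lm`
#'   fit.
#' @export
fit_nem_bfr <- function(bfr_values, nem) {
  if (length(bfr_values) < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(bfr_values) == 0) {
    stop("degenerate predictor: constant BFR", call. = FALSE)
  }
  f <- stats::lm(nem ~ bfr_values)
  cf <- stats::coef(f)
  list(slope = unname(cf[2]), intercept = unname(cf[1]),
       r_squared = ols_r2(f, nem), fit = f)
}

#' Combined light + hydrology model for NEM
#'
#' Additive bivariate OLS `NEM = a * PAR + b * BFR + c`. Because the
#' single-driver models are nested within it, its R^2 is never below
#' either single-driver R^2 on the same points.
#'
#' @param par_total daily streambed PAR integrals.
#' @param bfr_values windowed base-flow ratios.
#' @param nem whole-stream NEM (mmol m^-2 d^-1).
#' @return A list with `coefficients` (a, b, c), `predicted`,
#'   `r_squared` and the `lm` fit.
#' @export
combined_model <- function(par_total, bfr_values, nem) {
  if (length(nem) < 4) stop("need at least 4 points", call. = FALSE)
  X <- cbind(par_total, bfr_values)
  if (qr(cbind(1, X))$rank < 3) {
    stop("rank-deficient design: drivers are collinear", call. = FALSE)
  }
  f <- stats::lm(nem ~ par_total + bfr_values)
  cf <- stats::coef(f)
  list(coefficients = c(a = unname(cf["par_total"]),
                        b = unname(cf["bfr_values"]),
                        c = unname(cf["(Intercept)"])),
       predicted = as.numeric(stats::fitted(f)),
       r_squared = ols_r2(f, nem), fit = f)
}
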