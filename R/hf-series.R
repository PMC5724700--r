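#' High-frequency eddy-covariance series
#'
#' Container for raw aquatic eddy-covariance (AEC) data: three velocity
#' components, dissolved oxygen and instrument quality channels sampled
#' on a uniform grid. Stored as a data frame with a `sample_rate`
#' attribute; all velocities in m/s, oxygen in umol/L (numerically equal
#' to mmol/m^3), beam correlation in percent and signal-to-noise ratio
#' in dB.
#'
#' @param time sample times in seconds on a uniform grid.
#' @param u,v,w longitudinal, transverse and vertical velocity (m/s).
#' @param o2 dissolved oxygen concentration (umol/L).
#' @param beam_corr acoustic beam correlation (percent).
#' @param snr signal-to-noise ratio (dB).
#' @param sample_rate sampling frequency in Hz; one of 8, 16, 32, 64.
#'
#' @return An object of class `hf_series` (a data frame).
#' @export
hf_series <- function(time, u, v, w, o2,
                      beam_corr = rep(100, length(time)),
                      snr = rep(30, length(time)),
                      sample_rate) {
  if (!sample_rate %in% c(8, 16, 32, 64)) {
    stop("`sample_rate` must be one of 8, 16, 32 or 64 Hz", call. = FALSE)
  }
  n <- length(time)
  lens <- lengths(list(u, v, w, o2, beam_corr, snr))
  if (any(lens != n)) stop("all channels must have equal length", call. = FALSE)
  if (n >= 2) {
    dt <- diff(time)
    if (max(abs(dt - 1 / sample_rate)) > 1e-6 / sample_rate) {
      stop("`time` must be a uniform grid at `sample_rate`", call. = FALSE)
    }
  }
  out <- data.frame(time = time, u = u, v = v, w = w, o2 = o2,
                    beam_corr = beam_corr, snr = snr)
  attr(out, "sample_rate") <- sample_rate
  class(out) <- c("hf_series", "data.frame")
  out
}

#' @export
print.hf_series <- function(x, ...) {
  cat(sprintf("<hf_series> %d samples at %g Hz (%.1f min)\n",
              nrow(x), attr(x, "sample_rate"),
              nrow(x) / attr(x, "sample_rate") / 60))
  print(utils::head(as.data.frame(x), 4L))
  invisible(x)
}

#' Sampling rate of a high-frequency series
#' @param x an `hf_series`.
#' @return Sampling frequency in Hz.
#' @export
sample_rate <- function(x) {
  r <- attr(x, "sample_rate")
  if (is.null(r)) stop("object has no sample_rate attribute", call. = FALSE)
  r
}

#' Read / write high-frequency series as delimited text
#'
#' Plain comma-separated text with a header row and columns
#' `time,u,v,w,o2,beam_corr,snr` (units as in [hf_series()]); the
#' sampling rate is inferred from the time grid on read.
#'
#' @param path file path.
#' @param x an `hf_series` to write.
#' @return `read_hf_series()` returns an `hf_series`;
#'   `write_hf_series()` returns `path` invisibly.
#' @export
read_hf_series <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time", "u", "v", "w", "o2")
  if (!all(need %in% names(d))) {
    stop("input must have columns time,u,v,w,o2", call. = FALSE)
  }
  rate <- round(1 / stats::median(diff(d$time)))
  hf_series(d$time, d$u, d$v, d$w, d$o2,
            beam_corr = d$beam_corr %||% rep(100, nrow(d)),
            snr = d$snr %||% rep(30, nrow(d)),
            sample_rate = rate)
}

#' @rdname read_hf_series
#' @export
write_hf_series <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
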