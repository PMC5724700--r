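# Internal helpers shared across modules.

# Run `expr` under an explicit RNG seed without disturbing the caller's
# RNG stream. All generators funnel their `seed` argument through here so
# there is no hidden global state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Unit-variance AR(1) series; phi set from an integral timescale (s).
ar1_series <- function(n, sample_rate, timescale = 1) {
  phi <- exp(-1 / (sample_rate * timescale))
  x <- stats::filter(stats::rnorm(n, sd = sqrt(1 - phi^2)), phi,
                     method = "recursive")
  as.numeric(x)
}

stop_if_not_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name),
         call. = FALSE)
  }
  invisible(x)
}

# Linear interpolation over flagged samples, constant extrapolation at
# the edges. Used by quality control and despiking replacements.
interp_over <- function(x, bad) {
  if (!any(bad)) return(x)
  if (all(bad)) stop("cannot interpolate: no valid samples", call. = FALSE)
  idx <- seq_along(x)
  x[bad] <- stats::approx(idx[!bad], x[!bad], xout = idx[bad],
                          rule = 2)$y
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coefficient of determination of an lm fit, computed directly so that
# perfect fits do not trip summary.lm's degenerate-fit warning.
ols_r2 <- function(fit, y) {
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(NA_real_)
  1 - sum(stats::resid(fit)^2) / tss
}
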