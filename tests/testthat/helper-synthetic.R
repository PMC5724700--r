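# Shared fixtures built in code.

# Small clean turbulence record for fast unit tests.
quick_turbulence <- function(..., duration = 1800, seed = 101) {
  gen_turbulence(turbulence_spec(..., duration = duration, seed = seed))
}

# An hf_series wrapper around plain vectors at 8 Hz.
hf8 <- function(u, v = rep(0, length(u)), w = rep(0, length(u)),
                o2 = rep(300, length(u)), ...) {
  n <- length(u)
  hf_series(time = (seq_len(n) - 1) / 8, u = u, v = v, w = w, o2 = o2,
            sample_rate = 8, ...)
}

expect_rel_equal <- function(object, expected, rel_tol) {
  expect_lt(abs(object - expected), abs(expected) * rel_tol)
}
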