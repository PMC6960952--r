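# Shared fixtures. Trials are generated in code; the heavier default trial is
# built once per test file that needs it.

quick_params <- function(n_cycles = 4, seed = 1, ...) {
  gait_params(n_cycles = n_cycles, seed = seed, ...)
}

# Independent brute-force oracles -----------------------------------------

# Eq.-style jerk magnitude, one sample at a time.
bf_jerk <- function(ax, ay, az) {
  n <- length(ax)
  out <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    out[i] <- sqrt((ax[i + 1] - ax[i])^2 + (ay[i + 1] - ay[i])^2 +
                     (az[i + 1] - az[i])^2)
  }
  out
}

# Trailing truncated-window mean, one sample at a time.
bf_smooth <- function(ja, w) {
  n <- length(ja)
  out <- numeric(n)
  for (j in seq_len(n)) {
    lo <- max(1, j - w + 1)
    out[j] <- mean(ja[lo:j])
  }
  out
}

# Textbook Bland-Altman recomputation.
bf_bland_altman <- function(d) {
  m <- sum(d) / length(d)
  s <- sqrt(sum((d - m)^2) / (length(d) - 1))
  lo <- m - 1.96 * s
  hi <- m + 1.96 * s
  list(mean = m, sd = s, lo = lo, hi = hi,
       outside = sum(d < lo | d > hi))
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / max(sum(b^2), 1e-300))
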