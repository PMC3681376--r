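# Independent oracles used across the test files.

# Brute-force sample entropy: explicit embedding matrices and a vectorized
# Chebyshev distance matrix, counting matching template pairs directly.
sampen_brute <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  count_pairs <- function(k) {
    d <- matrix(0, nt, nt)
    for (j in 0:(k - 1)) {
      v <- x[(1:nt) + j]
      d <- pmax(d, abs(outer(v, v, "-")))
    }
    sum(d[upper.tri(d)] <= r)
  }
  b <- count_pairs(m)
  a <- count_pairs(m + 1)
  if (a == 0 || b == 0) return(NA_real_)
  -log(a / b)
}

# Fraction of periodogram power inside [f_lo, f_hi], zero frequency
# excluded.
periodogram_band_fraction <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  x <- x - mean(x)
  p <- Mod(fft(x))^2
  f <- (0:(n - 1)) / n * fs
  half <- 2:floor(n / 2)            # positive frequencies
  inside <- f[half] >= f_lo & f[half] <= f_hi
  sum(p[half][inside]) / sum(p[half])
}

# Frequency of the dominant periodogram peak.
periodogram_peak_freq <- function(x, fs) {
  n <- length(x)
  x <- x - mean(x)
  p <- Mod(fft(x))^2
  f <- (0:(n - 1)) / n * fs
  half <- 2:floor(n / 2)
  f[half][which.max(p[half])]
}

# Exact two-sided rank-sum p-value by full enumeration of group
# assignments (no ties assumed).
ranksum_exact_enum <- function(a, b) {
  vals <- c(a, b)
  n <- length(vals)
  rk <- rank(vals)
  w_obs <- sum(rk[seq_along(a)])
  combos <- utils::combn(n, length(a))
  w_all <- apply(combos, 2, function(idx) sum(rk[idx]))
  mu <- length(a) * (n + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Small preprocessed synthetic cohort shared by feature-level tests
# (about 34 minutes of signal; long enough for 9 dyadic scales).
make_tiny_cohort <- function(n_per_group = 2, seed = 42, duration_s = 20480,
                             artifact_rate = 0) {
  generate_cohort(default_group_profiles(),
                  cohort_config(n_per_group = n_per_group,
                                duration_s = duration_s,
                                artifact_rate = artifact_rate, seed = seed))
}
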