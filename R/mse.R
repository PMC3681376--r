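#' Coarse-grain a series
#'
#' Non-overlapping windows of length `tau` are averaged; the output has
#' length `floor(N / tau)` and a trailing partial window is dropped.
#'
#' @param x Numeric vector.
#' @param tau Integer scale factor (>= 1).
#' @return Numeric vector of length `floor(length(x) / tau)`.
#' @export
coarse_grain <- function(x, tau) {
  tau <- as.integer(tau)
  if (tau < 1) stop("tau must be >= 1")
  n <- length(x)
  if (tau > n) stop("tau exceeds the series length")
  if (tau == 1) return(x)
  m <- floor(n / tau)
  colMeans(matrix(x[seq_len(m * tau)], nrow = tau))
}

#' Sample entropy
#'
#' `SampEn(m, r) = -ln(A / B)` where `B` counts pairs of distinct `m`-length
#' templates within Chebyshev distance `r` and `A` counts the same pairs
#' still matching when extended by one point. Self-matches are excluded.
#' When no pairs match at either length the entropy is undefined and `NA`
#' is returned.
#'
#' @param x Numeric vector, length > `m + 1`.
#' @param m Embedding dimension (default 2).
#' @param r Absolute tolerance (same units as `x`); callers using the
#'   conventional fraction-of-SD tolerance should multiply by `sd(x)` or
#'   normalize `x` first.
#' @return Non-negative scalar, or `NA` when undefined.
#' @export
sample_entropy <- function(x, m = 2, r) {
  if (length(x) <= m + 1) stop("series too short for embedding dimension m")
  if (r <= 0) stop("tolerance r must be positive")
  sampen_cpp(as.numeric(x), as.integer(m), as.numeric(r))
}

#' Multiscale entropy curve
#'
#' The series is normalized to unit SD once, the tolerance `r` is fixed on
#' that scale (not re-estimated per coarse-grained series), and sample
#' entropy is computed on each coarse-grained series for scale factors
#' `tau = 1..n_scales`. `sumEn` is the sum of the defined per-scale values;
#' undefined scales (no template matches) are excluded and counted.
#'
#' @param x Numeric vector (a preprocessed temperature series).
#' @param m Embedding dimension (default 2).
#' @param r Tolerance as a fraction of the SD (default 0.15).
#' @param n_scales Largest coarse-graining factor (default 36).
#' @return An object of class `mse_result`: list with `curve` (data frame
#'   `tau`, `sampen`), `sum_en`, `base_sampen`, `n_undefined` and the
#'   parameters.
#' @export
mse_curve <- function(x, m = 2, r = 0.15, n_scales = 36) {
  if (inherits(x, "temp_signal")) x <- x$samples
  if (!(m >= 1)) stop("m must be >= 1")
  if (r <= 0 || r >= 1) stop("r must lie in (0, 1)")
  n <- length(x)
  bad <- which(floor(n / seq_len(n_scales)) <= m + 1)
  if (length(bad)) {
    stop(sprintf(
      "series too short for coarse-graining: tau = %d leaves %d points (need > %d)",
      bad[1], floor(n / bad[1]), m + 1))
  }
  s <- sd(x)
  if (s == 0) stop("zero-variance series")
  x <- x / s
  sampen <- vapply(seq_len(n_scales), function(tau) {
    sampen_cpp(coarse_grain(x, tau), as.integer(m), r)
  }, 1.0)
  structure(list(curve = data.frame(tau = seq_len(n_scales),
                                    sampen = sampen),
                 sum_en = sum(sampen, na.rm = TRUE),
                 base_sampen = sampen[1],
                 n_undefined = sum(is.na(sampen)),
                 m = m, r = r, n_scales = n_scales),
            class = "mse_result")
}

#' @export
print.mse_result <- function(x, ...) {
  cat(sprintf(
    "<mse_result> m=%d r=%.2f, %d scales (%d undefined), sumEn=%.3f, SampEn=%.4f\n",
    x$m, x$r, x$n_scales, x$n_undefined, x$sum_en, x$base_sampen))
  invisible(x)
}
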