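# Meyer wavelet machinery: FIR approximation of the discrete Meyer filter,
# a periodized pyramid DWT, and an FFT-based continuous transform using the
# analytic Meyer frequency response.

# Meyer auxiliary polynomial: C^3 monotone ramp from 0 to 1 on [0, 1].
meyer_nu <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x^4 * (35 - 84 * x + 70 * x^2 - 20 * x^3)
}

# Fourier transform of the Meyer scaling function (real, compactly supported
# on |w| <= 4*pi/3).
meyer_phi_hat <- function(w) {
  w <- abs(w)
  out <- numeric(length(w))
  out[w <= 2 * pi / 3] <- 1
  mid <- w > 2 * pi / 3 & w <= 4 * pi / 3
  out[mid] <- cos(pi / 2 * meyer_nu(3 * w[mid] / (2 * pi) - 1))
  out
}

#' Magnitude of the Meyer wavelet frequency response
#'
#' The band-pass response is supported on `2*pi/3 <= |w| <= 8*pi/3` with its
#' plateau peak at `|w| = 4*pi/3`, giving a centre frequency of 2/3
#' cycles/sample at unit scale. The linear phase factor is dropped
#' (zero-phase convention); only squared coefficients enter the features.
#'
#' @param w Angular frequency in radians per sample.
#' @return Numeric vector of response magnitudes.
#' @export
meyer_psi_hat <- function(w) {
  w <- abs(w)
  out <- numeric(length(w))
  i1 <- w >= 2 * pi / 3 & w <= 4 * pi / 3
  out[i1] <- sin(pi / 2 * meyer_nu(3 * w[i1] / (2 * pi) - 1))
  i2 <- w > 4 * pi / 3 & w <= 8 * pi / 3
  out[i2] <- cos(pi / 2 * meyer_nu(3 * w[i2] / (4 * pi) - 1))
  out
}

#' Discrete Meyer FIR filter pair
#'
#' Generates the orthonormal low-pass filter by frequency-sampling the
#' two-scale relation `H(w) = sqrt(2) * phi_hat(2 w)` on a dense grid,
#' inverse transforming, and truncating to `n_taps` centred taps (102 by
#' default, the customary discrete-Meyer length). The high-pass filter is
#' the conjugate quadrature mirror. Truncation leaves orthogonality errors
#' below 1e-8, small enough for energy conservation to hold to 1e-6 in a
#' periodized pyramid.
#'
#' @param n_taps Even number of filter taps.
#' @param grid_size Frequency-grid size used for the inverse transform.
#' @return List with low-pass `h` and high-pass `g` coefficient vectors.
#' @export
meyer_filter <- function(n_taps = 102, grid_size = 2^14) {
  stopifnot(n_taps %% 2 == 0, grid_size > 4 * n_taps)
  k <- 0:(grid_size - 1)
  w <- 2 * pi * k / grid_size
  w[w >= pi] <- w[w >= pi] - 2 * pi
  H <- sqrt(2) * meyer_phi_hat(2 * w)
  h_full <- Re(fft(H, inverse = TRUE)) / grid_size
  idx <- c((grid_size - n_taps / 2 + 1):grid_size, 1:(n_taps / 2))
  h <- h_full[idx]
  g <- rev(h) * (-1)^(0:(n_taps - 1))
  list(h = h, g = g)
}

# Wrap a filter onto length n (periodization): taps beyond n fold back.
periodize_filter <- function(f, n) {
  out <- numeric(n)
  for (k in seq_along(f)) {
    i <- (k - 1) %% n + 1
    out[i] <- out[i] + f[k]
  }
  out
}

# One analysis step of the periodized pyramid: circular correlation with the
# low- and high-pass filters followed by dyadic downsampling.
dwt_step <- function(x, h, g) {
  n <- length(x)
  fx <- fft(x)
  a <- Re(fft(fx * Conj(fft(periodize_filter(h, n))), inverse = TRUE)) / n
  d <- Re(fft(fx * Conj(fft(periodize_filter(g, n))), inverse = TRUE)) / n
  keep <- seq(1, n, by = 2)
  list(approx = a[keep], detail = d[keep])
}

#' Discrete Meyer wavelet decomposition
#'
#' Periodized pyramid DWT over `n_scales` dyadic levels. Scale `s_i` covers
#' the frequency band `[fs/2^(i+1), fs/2^i]`. Odd intermediate lengths are
#' extended by repeating the last sample before the next split (only
#' relevant when the length is not divisible by `2^n_scales`; energy
#' conservation is exact for dyadic lengths).
#'
#' @param x Numeric vector or [temp_signal].
#' @param n_scales Number of detail levels (default 9).
#' @param fs_hz Sampling frequency; taken from the signal if `x` is a
#'   [temp_signal].
#' @param filter Filter pair from [meyer_filter()].
#' @return An object of class `wavelet_decomp`: list with `details` (list of
#'   coefficient vectors, scales 1..n_scales), `approx`, `fs_hz`, `wavelet`
#'   and `boundary`.
#' @export
dwt_meyer <- function(x, n_scales = 9, fs_hz = NULL, filter = meyer_filter()) {
  if (inherits(x, "temp_signal")) {
    if (is.null(fs_hz)) fs_hz <- x$fs_hz
    x <- x$samples
  }
  if (is.null(fs_hz)) fs_hz <- 1
  n <- length(x)
  n_min <- 2^(n_scales + 1)
  if (n < n_min) {
    stop(sprintf(
      "signal too short for %d scales: %d samples given, %d required",
      n_scales, n, n_min))
  }
  a <- x
  details <- vector("list", n_scales)
  for (lev in seq_len(n_scales)) {
    if (length(a) %% 2 == 1) a <- c(a, a[length(a)])
    st <- dwt_step(a, filter$h, filter$g)
    details[[lev]] <- st$detail
    a <- st$approx
  }
  structure(list(details = details, approx = a, fs_hz = fs_hz,
                 wavelet = "discrete Meyer (102-tap FIR)",
                 boundary = "periodization"),
            class = "wavelet_decomp")
}

#' @export
print.wavelet_decomp <- function(x, ...) {
  cat(sprintf("<wavelet_decomp> %s, %s boundary, %d scales\n", x$wavelet,
              x$boundary, length(x$details)))
  cat("  detail lengths:", vapply(x$details, length, 1L), "\n")
  invisible(x)
}

#' Continuous Meyer wavelet transform
#'
#' FFT-based CWT against the analytic Meyer response at a grid of
#' pseudo-frequencies. Rows are ordered by decreasing frequency. Coefficients
#' use the L1-normalized convention (`psi_hat(a w)` without amplitude
#' re-weighting), under which a pure oscillation attains its ridge maximum
#' exactly at its own pseudo-frequency.
#'
#' @param x Numeric vector or [temp_signal].
#' @param fs_hz Sampling frequency.
#' @param freqs_hz Pseudo-frequency grid; defaults to 64 logarithmically
#'   spaced values spanning `[fs/2^10, fs/2]`. Values outside `(0, fs/2]`
#'   are an error.
#' @param n_freqs Number of grid frequencies when `freqs_hz` is `NULL`.
#' @return An object of class `cwt_map`: coefficient matrix
#'   (`n_freqs` x `N`) with attribute `pseudo_freq_hz`.
#' @export
cwt_meyer <- function(x, fs_hz = NULL, freqs_hz = NULL, n_freqs = 64) {
  if (inherits(x, "temp_signal")) {
    if (is.null(fs_hz)) fs_hz <- x$fs_hz
    x <- x$samples
  }
  if (is.null(fs_hz)) stop("fs_hz is required")
  if (is.null(freqs_hz)) {
    freqs_hz <- exp(seq(log(fs_hz / 2), log(fs_hz / 2^10),
                        length.out = n_freqs))
    freqs_hz <- pmin(freqs_hz, fs_hz / 2)   # guard rounding at the top edge
  }
  if (length(freqs_hz) == 0) stop("pseudo-frequency grid is empty")
  if (any(freqs_hz <= 0 | freqs_hz > fs_hz / 2)) {
    stop("pseudo-frequencies must lie in (0, fs/2]")
  }
  freqs_hz <- sort(freqs_hz, decreasing = TRUE)
  n <- length(x)
  fx <- fft(x)
  om <- 2 * pi * (0:(n - 1)) / n
  om[om >= pi] <- om[om >= pi] - 2 * pi
  centre <- 2 / 3  # cycles/sample at unit scale
  map <- t(vapply(freqs_hz, function(f0) {
    a <- centre / (f0 / fs_hz)
    Re(fft(fx * meyer_psi_hat(a * om), inverse = TRUE)) / n
  }, numeric(n)))
  structure(map, pseudo_freq_hz = freqs_hz, fs_hz = fs_hz, class = "cwt_map")
}

#' @export
print.cwt_map <- function(x, ...) {
  f <- attr(x, "pseudo_freq_hz")
  cat(sprintf("<cwt_map> %d scales x %d samples, %.3g-%.3g Hz\n", nrow(x),
              ncol(x), min(f), max(f)))
  invisible(x)
}
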