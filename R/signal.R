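#' Temperature signal container
#'
#' A `temp_signal` holds one continuously recorded temperature series together
#' with its sampling frequency, an artifact mask, identifiers and a
#' preprocessing variant tag. The mask is a two-column integer matrix of
#' half-open, 0-based sample-index intervals `[start, end)`; intervals must be
#' disjoint, sorted and inside `[0, N)`.
#'
#' @param samples Numeric vector of temperatures (degrees Celsius).
#' @param fs_hz Sampling frequency in Hz (default 0.1, one sample per 10 s).
#' @param mask Two-column matrix of half-open 0-based index intervals, or
#'   `NULL` for no artifacts.
#' @param subject_id Subject identifier.
#' @param group Optional group label (e.g. `"SIRS"`, `"sepsis"`,
#'   `"septic_shock"`).
#' @param sofa Optional SOFA severity score.
#' @param variant Preprocessing variant: `"raw"`, `"sign_m"` (mean removed) or
#'   `"sign_mdetr"` (mean and linear trend removed).
#' @return An object of class `temp_signal`.
#' @export
temp_signal <- function(samples, fs_hz = 0.1, mask = NULL, subject_id = "s1",
                        group = NA_character_, sofa = NA_real_,
                        variant = c("raw", "sign_m", "sign_mdetr")) {
  variant <- match.arg(variant)
  if (!is.numeric(samples) || length(samples) == 0) {
    stop("samples must be a non-empty numeric vector")
  }
  if (!is.numeric(fs_hz) || length(fs_hz) != 1 || fs_hz <= 0) {
    stop("fs_hz must be a single positive number")
  }
  mask <- validate_mask(mask, length(samples))
  structure(
    list(samples = as.numeric(samples), fs_hz = fs_hz, mask = mask,
         subject_id = subject_id, group = group, sofa = sofa,
         variant = variant),
    class = "temp_signal")
}

# Normalizes a mask to a sorted 2-column integer matrix and checks that the
# intervals are non-empty, disjoint and inside [0, n).
validate_mask <- function(mask, n) {
  if (is.null(mask) || (is.matrix(mask) && nrow(mask) == 0)) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  mask <- matrix(as.integer(mask), ncol = 2,
                 dimnames = list(NULL, c("start", "end")))
  mask <- mask[order(mask[, 1]), , drop = FALSE]
  if (any(mask[, 2] <= mask[, 1])) stop("mask intervals must be non-empty")
  if (any(mask[, 1] < 0) || any(mask[, 2] > n)) {
    stop("mask intervals must lie within [0, N)")
  }
  if (nrow(mask) > 1 && any(mask[-1, 1] < mask[-nrow(mask), 2])) {
    stop("mask intervals must be disjoint")
  }
  mask
}

#' @export
print.temp_signal <- function(x, ...) {
  cat(sprintf("<temp_signal> %s  variant=%s  group=%s\n", x$subject_id,
              x$variant, x$group))
  cat(sprintf("  %d samples @ %.3g Hz (%.2f h), %d artifact interval(s)\n",
              length(x$samples), x$fs_hz,
              length(x$samples) / x$fs_hz / 3600, nrow(x$mask)))
  invisible(x)
}

#' @export
length.temp_signal <- function(x) length(x$samples)

#' Convert second-based artifact intervals to a sample-index mask
#'
#' Interval files annotate artifacts in seconds; internally masks are
#' half-open 0-based sample indices. The conversion is
#' `floor(start_s * fs)` to `ceiling(end_s * fs)` so the masked region always
#' covers the annotated one.
#'
#' @param intervals Data frame or matrix with columns `start_s`, `end_s`.
#' @param fs_hz Sampling frequency (Hz).
#' @param n Number of samples (intervals are clipped to `[0, n)`).
#' @return Two-column integer matrix of index intervals.
#' @export
mask_from_seconds <- function(intervals, fs_hz, n) {
  if (is.null(intervals) || nrow(intervals) == 0) {
    return(validate_mask(NULL, n))
  }
  intervals <- as.data.frame(intervals)
  start <- pmax(0L, as.integer(floor(intervals$start_s * fs_hz)))
  end <- pmin(as.integer(n), as.integer(ceiling(intervals$end_s * fs_hz)))
  validate_mask(cbind(start, end), n)
}

#' Write / read a temperature signal as CSV
#'
#' The on-disk format is a plain CSV with columns `time_s` and `temp_C`;
#' artifact masks travel in a companion CSV with columns `start_s`, `end_s`.
#'
#' @param signal A [temp_signal].
#' @param file Path to the signal CSV.
#' @param mask_file Optional path for the artifact-interval CSV.
#' @return `write_signal_csv` returns `file` invisibly; `read_signal_csv`
#'   returns a [temp_signal].
#' @export
write_signal_csv <- function(signal, file, mask_file = NULL) {
  stopifnot(inherits(signal, "temp_signal"))
  n <- length(signal$samples)
  df <- data.frame(time_s = (seq_len(n) - 1) / signal$fs_hz,
                   temp_C = signal$samples)
  write.csv(df, file, row.names = FALSE)
  if (!is.null(mask_file)) {
    mdf <- data.frame(start_s = signal$mask[, 1] / signal$fs_hz,
                      end_s = signal$mask[, 2] / signal$fs_hz)
    write.csv(mdf, mask_file, row.names = FALSE)
  }
  invisible(file)
}

#' @rdname write_signal_csv
#' @param fs_hz Sampling frequency; if `NULL`, inferred from the `time_s`
#'   column spacing.
#' @param subject_id,group,sofa Metadata attached to the returned signal.
#' @export
read_signal_csv <- function(file, mask_file = NULL, fs_hz = NULL,
                            subject_id = basename(file),
                            group = NA_character_, sofa = NA_real_) {
  df <- read.csv(file)
  required <- c("time_s", "temp_C")
  if (!all(required %in% names(df))) {
    stop(sprintf("%s: expected columns time_s, temp_C", file))
  }
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    warning(sprintf("%s: ignoring unknown column(s): %s", file,
                    paste(extra, collapse = ", ")))
  }
  if (anyNA(df$temp_C)) {
    stop(sprintf("%s: missing temp_C value at line %d", file,
                 which(is.na(df$temp_C))[1] + 1L))
  }
  if (is.null(fs_hz)) {
    dt <- median(diff(df$time_s))
    if (!is.finite(dt) || dt <= 0) stop(sprintf("%s: cannot infer fs", file))
    fs_hz <- 1 / dt
  }
  mask <- NULL
  if (!is.null(mask_file) && file.exists(mask_file)) {
    mdf <- read.csv(mask_file)
    mask <- mask_from_seconds(mdf, fs_hz, nrow(df))
  }
  temp_signal(df$temp_C, fs_hz = fs_hz, mask = mask, subject_id = subject_id,
              group = group, sofa = sofa)
}
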