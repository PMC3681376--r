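#' Repair annotated artifact segments by linear interpolation
#'
#' Each masked interval is replaced by the straight line connecting the last
#' clean sample before the interval and the first clean sample after it.
#' Masks touching the first or last sample are extended with the nearest
#' clean value (flat) with a warning; a mask covering the whole signal is an
#' error. Samples outside the mask are returned bit-identical.
#'
#' @param signal A [temp_signal] with a valid artifact mask.
#' @return The repaired [temp_signal] (mask retained for provenance).
#' @export
replace_artifacts <- function(signal) {
  stopifnot(inherits(signal, "temp_signal"))
  x <- signal$samples
  n <- length(x)
  if (n < 2) stop("signal must have at least 2 samples")
  mask <- signal$mask
  if (nrow(mask) == 0) return(signal)
  clean <- rep(TRUE, n)
  for (i in seq_len(nrow(mask))) clean[(mask[i, 1] + 1):mask[i, 2]] <- FALSE
  if (!any(clean)) stop("mask covers the whole signal; nothing to repair")
  for (i in seq_len(nrow(mask))) {
    lo <- mask[i, 1]            # 0-based: masked samples are lo..hi-1
    hi <- mask[i, 2]
    idx <- (lo + 1):hi          # 1-based masked positions
    left <- if (lo >= 1) lo else NA        # 1-based clean neighbour before
    right <- if (hi < n) hi + 1 else NA    # 1-based clean neighbour after
    if (is.na(left) && is.na(right)) stop("mask covers the whole signal")
    if (is.na(left)) {
      warning("mask touches the signal start; extending first clean value")
      x[idx] <- x[right]
    } else if (is.na(right)) {
      warning("mask touches the signal end; extending last clean value")
      x[idx] <- x[left]
    } else {
      gap <- right - left
      x[idx] <- x[left] + (x[right] - x[left]) * (idx - left) / gap
    }
  }
  out <- signal
  out$samples <- x
  out
}

#' Subtract the signal mean
#'
#' Produces the `sign_m` analysis variant: the average value is removed so
#' that downstream features are not biased by the temperature mean.
#'
#' @param signal A [temp_signal]; artifacts should already be repaired.
#' @return A [temp_signal] with variant `"sign_m"` and zero mean.
#' @export
remove_mean <- function(signal) {
  stopifnot(inherits(signal, "temp_signal"))
  if (length(signal$samples) == 0) stop("empty signal")
  out <- signal
  out$samples <- signal$samples - mean(signal$samples)
  out$variant <- "sign_m"
  out
}

#' Remove the least-squares linear trend
#'
#' Produces the `sign_mdetr` variant from a mean-removed signal: a straight
#' line fit by ordinary least squares over the full record is subtracted, so
#' the output is orthogonal to both the constant and the linear regressor.
#'
#' @param signal A [temp_signal] with variant `"sign_m"`.
#' @return A [temp_signal] with variant `"sign_mdetr"`.
#' @export
detrend_linear <- function(signal) {
  stopifnot(inherits(signal, "temp_signal"))
  if (signal$variant != "sign_m") {
    stop("detrend_linear expects a mean-removed (sign_m) signal")
  }
  x <- signal$samples
  n <- length(x)
  if (n < 2) stop("signal must have at least 2 samples")
  t <- seq_len(n)
  fit <- lm.fit(cbind(1, t), x)
  out <- signal
  out$samples <- unname(fit$residuals)
  out$samples <- out$samples - mean(out$samples)  # guard rounding
  out$variant <- "sign_mdetr"
  out
}

#' Run the full preprocessing chain
#'
#' Applies the sanctioned order: artifact repair, mean removal, linear
#' detrending, and returns both analysis variants.
#'
#' @param signal A raw [temp_signal].
#' @param auto_flag If `TRUE`, jumps larger than `flag_threshold_c` between
#'   consecutive samples are added to the artifact mask before repair
#'   (off by default; annotation is normally manual).
#' @param flag_threshold_c Jump threshold in degrees Celsius.
#' @return List with elements `sign_m` and `sign_mdetr`.
#' @export
preprocess_signal <- function(signal, auto_flag = FALSE,
                              flag_threshold_c = 0.5) {
  stopifnot(inherits(signal, "temp_signal"))
  if (auto_flag) signal <- flag_artifacts(signal, flag_threshold_c)
  repaired <- replace_artifacts(signal)
  sm <- remove_mean(repaired)
  list(sign_m = sm, sign_mdetr = detrend_linear(sm))
}

#' Flag suspect jumps as artifacts
#'
#' Simple automatic annotation: any sample-to-sample change larger than
#' `threshold_c` marks the two flanking samples as an artifact interval.
#' Flagged intervals are merged with the existing mask.
#'
#' @param signal A [temp_signal].
#' @param threshold_c Absolute jump threshold in degrees Celsius.
#' @return The [temp_signal] with an augmented mask.
#' @export
flag_artifacts <- function(signal, threshold_c = 0.5) {
  stopifnot(inherits(signal, "temp_signal"))
  d <- abs(diff(signal$samples))
  hits <- which(d > threshold_c)
  if (length(hits) == 0) return(signal)
  iv <- cbind(hits - 1L, hits + 1L)        # 0-based half-open around the jump
  merged <- merge_intervals(rbind(signal$mask, iv), length(signal$samples))
  out <- signal
  out$mask <- merged
  out
}

# Merge possibly overlapping half-open intervals into a disjoint sorted mask.
merge_intervals <- function(iv, n) {
  if (nrow(iv) == 0) return(validate_mask(NULL, n))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    last <- nrow(out)
    if (iv[i, 1] <= out[last, 2]) {
      out[last, 2] <- max(out[last, 2], iv[i, 2])
    } else {
      out <- rbind(out, iv[i, ])
    }
  }
  validate_mask(out, n)
}
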