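#' Dyadic scale-to-frequency band map
#'
#' For a sampling frequency `fs`, DWT scale `i` covers the frequency band
#' `[fs/2^(i+1), fs/2^i]` Hz; oscillation periods are reported in minutes
#' (`1/(60 f)`). At 0.1 Hz, scale 1 is attributed to neurogenic inputs,
#' scales 2-3 to metabolic inputs, and scales 4 and deeper to ultradian
#' influences.
#'
#' @param fs_hz Sampling frequency in Hz.
#' @param n_scales Number of dyadic scales.
#' @return Data frame with columns `scale`, `f_min_hz`, `f_max_hz`,
#'   `period_min_min`, `period_max_min`, `tag`.
#' @export
scale_frequency_bands <- function(fs_hz = 0.1, n_scales = 9) {
  stopifnot(fs_hz > 0, n_scales >= 1)
  i <- seq_len(n_scales)
  f_max <- fs_hz / 2^i
  f_min <- fs_hz / 2^(i + 1)
  tag <- ifelse(i == 1, "neurogenic", ifelse(i <= 3, "metabolic",
                                             "ultradian"))
  data.frame(scale = i, f_min_hz = f_min, f_max_hz = f_max,
             period_min_min = 1 / (60 * f_max),
             period_max_min = 1 / (60 * f_min), tag = tag)
}

#' Wavelet energy of one scale
#'
#' Mean squared detail coefficient at scale `s`:
#' `WE(s) = sum_j w(s, j)^2 / L_s`.
#'
#' @param decomp A `wavelet_decomp` from [dwt_meyer()], or a plain numeric
#'   coefficient vector.
#' @param s Scale index (ignored when `decomp` is a plain vector).
#' @return Non-negative scalar.
#' @export
wavelet_energy <- function(decomp, s = NULL) {
  w <- scale_coefficients(decomp, s)
  if (length(w) == 0) stop("empty coefficient vector")
  mean(w^2)
}

#' Shannon wavelet entropy of one scale
#'
#' Squared coefficients at scale `s` are normalized to a probability
#' distribution over time positions, `p_j = w_j^2 / sum_j w_j^2`, and the
#' Shannon entropy `-sum p_j log p_j` is returned. Zero-probability terms
#' contribute 0; an all-zero scale is defined as entropy 0 with a warning.
#' With `normalized = TRUE` the entropy is divided by `log(L_s)`, giving a
#' value in \[0, 1\].
#'
#' @inheritParams wavelet_energy
#' @param base Logarithm base: `"natural"` (default), `"2"` or `"10"`.
#' @param normalized Divide by the maximal entropy `log(L_s)`?
#' @return Entropy in `[0, log(L_s)]` (or `[0, 1]` when normalized).
#' @export
wavelet_entropy <- function(decomp, s = NULL,
                            base = c("natural", "2", "10"),
                            normalized = FALSE) {
  base <- match.arg(base)
  w <- scale_coefficients(decomp, s)
  if (length(w) == 0) stop("empty coefficient vector")
  shannon(w^2, base = base, normalized = normalized,
          zero_label = sprintf("scale %s", if (is.null(s)) "?" else s))
}

scale_coefficients <- function(decomp, s) {
  if (inherits(decomp, "wavelet_decomp")) {
    if (is.null(s) || s < 1 || s > length(decomp$details)) {
      stop(sprintf("scale index must lie in 1..%d", length(decomp$details)))
    }
    decomp$details[[s]]
  } else {
    as.numeric(decomp)
  }
}

log_fun <- function(base) {
  switch(base, natural = log, "2" = log2, "10" = log10)
}

# Shannon entropy of a non-negative weight vector (normalized internally).
shannon <- function(w2, base = "natural", normalized = FALSE,
                    zero_label = "input") {
  lg <- log_fun(base)
  tot <- sum(w2)
  if (tot == 0) {
    warning(sprintf("all coefficients are zero at %s; entropy defined as 0",
                    zero_label))
    return(0)
  }
  p <- w2 / tot
  p <- p[p > 0]
  h <- -sum(p * lg(p))
  if (normalized) h <- h / lg(length(w2))
  h
}

#' Default CWT frequency bands
#'
#' Four bands partitioning the analyzed range `[fs/2^10, fs/2]`: neurogenic
#' `[fs/4, fs/2]`, metabolic `[fs/16, fs/4]`, lower-metabolic/ultradian
#' `[fs/64, fs/16]` and ultradian `[fs/2^10, fs/64]`. At 0.1 Hz these are
#' 0.025-0.05, 0.00625-0.025, 0.0015625-0.00625 and 0.0000977-0.0015625 Hz.
#'
#' @param fs_hz Sampling frequency.
#' @return Data frame with columns `band`, `f_lo_hz`, `f_hi_hz`.
#' @export
default_cwt_bands <- function(fs_hz = 0.1) {
  data.frame(band = 1:4,
             f_lo_hz = c(fs_hz / 4, fs_hz / 16, fs_hz / 64, fs_hz / 2^10),
             f_hi_hz = c(fs_hz / 2, fs_hz / 4, fs_hz / 16, fs_hz / 64))
}

#' Energy and entropy features of a CWT map
#'
#' Computes wavelet energy (mean squared coefficient) and Shannon entropy of
#' the squared-coefficient distribution for the whole time-scale map and for
#' each frequency band, yielding the 10 features `CWTen`, `CWTentro`,
#' `CWTen1..4`, `CWTentro1..4`. Entropies are reported normalized by the log
#' of the number of cells (a \[0, 1\] index); the raw entropies are also
#' returned under a `_raw` suffix.
#'
#' @param map A `cwt_map` from [cwt_meyer()].
#' @param bands Band definition as from [default_cwt_bands()].
#' @param base Logarithm base for the entropies.
#' @return Named numeric vector of 10 features plus `_raw` entropy variants.
#' @export
cwt_band_features <- function(map, bands = NULL,
                              base = c("natural", "2", "10")) {
  base <- match.arg(base)
  stopifnot(inherits(map, "cwt_map"))
  fs <- attr(map, "fs_hz")
  if (is.null(bands)) bands <- default_cwt_bands(fs)
  freqs <- attr(map, "pseudo_freq_hz")
  w2 <- unclass(map)^2
  out <- c(CWTen = mean(w2),
           CWTentro = shannon(w2, base, normalized = TRUE,
                              zero_label = "whole map"))
  raw <- c(CWTentro_raw = shannon(w2, base, zero_label = "whole map"))
  for (b in seq_len(nrow(bands))) {
    rows <- freqs > bands$f_lo_hz[b] & freqs <= bands$f_hi_hz[b]
    if (!any(rows)) {
      stop(sprintf("CWT band %d (%.3g-%.3g Hz) contains no scales",
                   bands$band[b], bands$f_lo_hz[b], bands$f_hi_hz[b]))
    }
    m <- w2[rows, , drop = FALSE]
    lbl <- sprintf("band %d", bands$band[b])
    out[paste0("CWTen", bands$band[b])] <- mean(m)
    out[paste0("CWTentro", bands$band[b])] <-
      shannon(m, base, normalized = TRUE, zero_label = lbl)
    raw[paste0("CWTentro", bands$band[b], "_raw")] <-
      shannon(m, base, zero_label = lbl)
  }
  c(out, raw)
}

#' All wavelet features of one preprocessed signal
#'
#' 18 DWT features (energy and entropy at scales 1..`n_scales`) plus the 10
#' CWT band features. DWT entropies are emitted both raw (`WEn_s*`, natural
#' log by default) and normalized by `log(L)` (`WEnn_s*`).
#'
#' @param signal A preprocessed [temp_signal] (variant `sign_m` or
#'   `sign_mdetr`).
#' @param n_scales Number of DWT scales.
#' @param base Logarithm base for entropies.
#' @param filter Meyer filter pair.
#' @return Named numeric vector.
#' @export
wavelet_features <- function(signal, n_scales = 9,
                             base = c("natural", "2", "10"),
                             filter = meyer_filter()) {
  base <- match.arg(base)
  dec <- dwt_meyer(signal, n_scales = n_scales, filter = filter)
  we <- vapply(seq_len(n_scales), function(s) wavelet_energy(dec, s), 1.0)
  wen <- vapply(seq_len(n_scales), function(s)
    wavelet_entropy(dec, s, base = base), 1.0)
  wenn <- vapply(seq_len(n_scales), function(s)
    wavelet_entropy(dec, s, base = base, normalized = TRUE), 1.0)
  map <- cwt_meyer(signal)
  c(setNames(we, paste0("WE_s", seq_len(n_scales))),
    setNames(wen, paste0("WEn_s", seq_len(n_scales))),
    setNames(wenn, paste0("WEnn_s", seq_len(n_scales))),
    cwt_band_features(map, base = base))
}

#' Assemble the subject-by-feature table for a cohort
#'
#' Preprocesses every signal, computes per subject and per variant the 18
#' DWT features, the 10 CWT band features, the raw-signal mean and SD, and
#' (optionally) the multiscale-entropy summaries `SampEn` and `sumEn`.
#'
#' @param cohort List of raw [temp_signal] objects (e.g. from
#'   [generate_cohort()] or [read_cohort_csv()]).
#' @param variants Character subset of `c("sign_m", "sign_mdetr")`.
#' @param mse Compute multiscale entropy features (the slowest step)?
#' @param mse_scales Number of coarse-graining factors for [mse_curve()].
#' @param n_scales,base,filter Passed to [wavelet_features()].
#' @return Data frame with columns `subject_id`, `group`, `sofa`, `variant`,
#'   `T_mean`, `T_sd`, the wavelet feature columns, and `SampEn`, `sumEn`
#'   when `mse = TRUE`.
#' @export
extract_feature_table <- function(cohort,
                                  variants = c("sign_m", "sign_mdetr"),
                                  mse = TRUE, mse_scales = 36, n_scales = 9,
                                  base = "natural",
                                  filter = meyer_filter()) {
  variants <- match.arg(variants, c("sign_m", "sign_mdetr"),
                        several.ok = TRUE)
  rows <- list()
  for (sig in cohort) {
    pp <- preprocess_signal(sig)
    for (v in variants) {
      s <- pp[[v]]
      feats <- wavelet_features(s, n_scales = n_scales, base = base,
                                filter = filter)
      if (mse) {
        mres <- mse_curve(s$samples, n_scales = mse_scales)
        feats <- c(feats, SampEn = mres$base_sampen, sumEn = mres$sum_en)
      }
      rows[[length(rows) + 1]] <- cbind(
        data.frame(subject_id = sig$subject_id, group = sig$group,
                   sofa = sig$sofa, variant = v,
                   T_mean = mean(sig$samples), T_sd = sd(sig$samples)),
        as.data.frame(as.list(feats)))
    }
  }
  do.call(rbind, rows)
}

#' Names of the canonical candidate feature pool
#'
#' The default pool used for clustering subsets and wrapper feature
#' selection: the 18 DWT features, the 10 CWT features, `SampEn`, `sumEn`,
#' and the raw-signal `T_mean` and `T_sd`. Normalized-entropy duplicates are
#' excluded.
#'
#' @param feature_table Optional feature table; when given, only columns
#'   actually present are returned.
#' @param n_scales Number of DWT scales.
#' @return Character vector of column names.
#' @export
feature_pool <- function(feature_table = NULL, n_scales = 9) {
  pool <- c(paste0("WE_s", seq_len(n_scales)),
            paste0("WEn_s", seq_len(n_scales)),
            "CWTen", "CWTentro", paste0("CWTen", 1:4),
            paste0("CWTentro", 1:4), "SampEn", "sumEn", "T_mean", "T_sd")
  if (!is.null(feature_table)) pool <- intersect(pool, names(feature_table))
  pool
}
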