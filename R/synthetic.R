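#' Frequency bands of skin-temperature oscillations
#'
#' Canonical physiological bands used by the synthetic generator: neurogenic
#' (0.025-0.05 Hz, sympathetic vasomotion), metabolic (0.00625-0.025 Hz,
#' endothelial activity) and ultradian (below 0.00625 Hz, slow rhythms of
#' unknown origin). The lower ultradian edge is tied to the deepest dyadic
#' analysis scale, `fs / 2^10`.
#'
#' @param fs_hz Sampling frequency (Hz).
#' @return Named list of `c(f_lo, f_hi)` pairs in Hz.
#' @export
physiological_bands <- function(fs_hz = 0.1) {
  list(neurogenic = c(fs_hz / 4, fs_hz / 2),
       metabolic = c(fs_hz / 16, fs_hz / 4),
       ultradian = c(fs_hz / 2^10, fs_hz / 16))
}

#' Group profile for the synthetic-cohort generator
#'
#' A profile describes the signal structure of one patient group: a baseline
#' temperature, a slow linear drift, and per-band oscillatory components whose
#' character is set by a regularity knob. Regularity 0 gives 1/f-weighted
#' band-limited Gaussian noise (broadband, irregular, high entropy);
#' regularity 1 gives a constant-amplitude oscillation whose frequency drifts
#' slowly across the band (organized, low entropy). The two endpoints carry
#' roughly equal energy per octave, so regularity moves complexity measures
#' without moving band energy.
#'
#' @param name Group label.
#' @param baseline_c Mean temperature in degrees Celsius (must lie in
#'   \[35, 41\]).
#' @param trend_c_per_h Linear drift in degrees Celsius per hour.
#' @param band_amplitudes Named numeric vector of per-band component SDs
#'   (degrees Celsius); names must match `bands`.
#' @param band_regularity Named numeric vector in \[0, 1\], same names.
#' @param noise_sd_c SD of white measurement noise (degrees Celsius).
#' @param baseline_sd_c Between-subject SD of the baseline (degrees Celsius);
#'   0 means every subject shares `baseline_c` exactly.
#' @param sofa_range Integer range `c(lo, hi)` from which synthetic SOFA
#'   scores are drawn uniformly.
#' @param bands Named list of `c(f_lo, f_hi)` band edges in Hz; defaults to
#'   [physiological_bands()]. Extra custom bands are allowed as long as the
#'   amplitude and regularity vectors name them.
#' @return An object of class `group_profile`.
#' @export
group_profile <- function(name, baseline_c = 38.0, trend_c_per_h = 0,
                          band_amplitudes = c(neurogenic = 0.02,
                                              metabolic = 0.05,
                                              ultradian = 0.3),
                          band_regularity = c(neurogenic = 0.5,
                                              metabolic = 0.5,
                                              ultradian = 0.5),
                          noise_sd_c = 0.01, baseline_sd_c = 0,
                          sofa_range = c(8L, 12L),
                          bands = physiological_bands()) {
  if (baseline_c < 35 || baseline_c > 41) {
    stop("baseline_c must lie in [35, 41] degrees C")
  }
  if (any(band_amplitudes < 0)) stop("band amplitudes must be >= 0")
  if (any(band_regularity < 0 | band_regularity > 1)) {
    stop("band regularity must lie in [0, 1]")
  }
  if (noise_sd_c < 0 || baseline_sd_c < 0) stop("noise SDs must be >= 0")
  bn <- names(bands)
  if (!setequal(names(band_amplitudes), bn) ||
      !setequal(names(band_regularity), bn)) {
    stop("band_amplitudes and band_regularity must name every band")
  }
  structure(list(name = name, baseline_c = baseline_c,
                 trend_c_per_h = trend_c_per_h,
                 band_amplitudes = band_amplitudes[bn],
                 band_regularity = band_regularity[bn],
                 noise_sd_c = noise_sd_c, baseline_sd_c = baseline_sd_c,
                 sofa_range = as.integer(sofa_range), bands = bands),
            class = "group_profile")
}

#' Synthetic cohort configuration
#'
#' @param n_per_group Subjects per profile; a scalar, or a vector with one
#'   entry per profile.
#' @param duration_s Recording length in seconds (default 24 h).
#' @param fs_hz Sampling frequency (default 0.1 Hz, one sample per 10 s).
#' @param quantization_c Sensor resolution in degrees Celsius (default
#'   0.05); 0 disables quantization.
#' @param artifact_rate Expected number of injected artifact segments per
#'   signal (Poisson); 0 disables artifacts.
#' @param artifact_max_len_s Maximum artifact length in seconds.
#' @param seed RNG seed for the whole cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 20, duration_s = 86400, fs_hz = 0.1,
                          quantization_c = 0.05, artifact_rate = 0,
                          artifact_max_len_s = 600, seed = 1) {
  if (duration_s <= 0 || fs_hz <= 0) {
    stop("invalid config: duration_s and fs_hz must be positive")
  }
  if (floor(duration_s * fs_hz) < 2^10) {
    stop("invalid config: duration_s * fs_hz must be at least 2^10 samples")
  }
  if (quantization_c < 0 || artifact_rate < 0) {
    stop("invalid config: quantization_c and artifact_rate must be >= 0")
  }
  structure(list(n_per_group = n_per_group, duration_s = duration_s,
                 fs_hz = fs_hz, quantization_c = quantization_c,
                 artifact_rate = artifact_rate,
                 artifact_max_len_s = artifact_max_len_s, seed = seed),
            class = "cohort_config")
}

# 1/f-weighted band-limited Gaussian noise, unit SD. Brick-wall band edges in
# the frequency domain give exact band control; the 1/f weight yields equal
# power per octave, matching the sweep endpoint of the regularity knob.
pink_band_noise <- function(n, f_lo, f_hi, fs_hz) {
  fz <- fft(rnorm(n))
  f <- (0:(n - 1)) / n * fs_hz
  f <- pmin(f, fs_hz - f)
  w <- numeric(n)
  keep <- f >= f_lo & f <= f_hi
  if (!any(keep)) stop("band contains no Fourier frequencies")
  w[keep] <- 1 / sqrt(f[keep])
  x <- Re(fft(fz * w, inverse = TRUE)) / n
  x / sd(x)
}

# Slowly drifting oscillation: a unit-SD sinusoid whose instantaneous
# frequency sweeps the band triangularly in log-frequency, so it spends equal
# time per octave. Random sweep phase and carrier phase per call.
fm_sweep <- function(n, f_lo, f_hi, fs_hz, sweep_period_s = 28800) {
  t <- (0:(n - 1)) / fs_hz
  u <- (t / sweep_period_s + runif(1)) %% 1
  s <- 2 * abs(u - 0.5)
  f_inst <- f_lo * (f_hi / f_lo)^s
  x <- sin(2 * pi * cumsum(f_inst) / fs_hz + runif(1, 0, 2 * pi))
  x / sd(x)
}

#' Generate one synthetic temperature recording
#'
#' The signal model is baseline + linear trend + per-band components + white
#' noise, rounded to the sensor quantization grid. Each band component mixes
#' the two regularity endpoints:
#' `amp * ((1 - reg) * pink_band_noise + reg * fm_sweep)`.
#'
#' @param profile A [group_profile].
#' @param config A [cohort_config].
#' @param seed Integer seed; the output is deterministic given `seed`.
#' @return A [temp_signal] with variant `"raw"` and an empty artifact mask.
#' @export
generate_subject <- function(profile, config, seed = 1) {
  stopifnot(inherits(profile, "group_profile"),
            inherits(config, "cohort_config"))
  set.seed(seed)
  n <- floor(config$duration_s * config$fs_hz)
  fs <- config$fs_hz
  t <- (0:(n - 1)) / fs
  x <- profile$baseline_c + rnorm(1, 0, profile$baseline_sd_c) +
    profile$trend_c_per_h * t / 3600
  for (b in names(profile$bands)) {
    amp <- profile$band_amplitudes[[b]]
    if (amp == 0) next
    reg <- profile$band_regularity[[b]]
    e <- profile$bands[[b]]
    comp <- numeric(n)
    if (reg < 1) comp <- comp + (1 - reg) * pink_band_noise(n, e[1], e[2], fs)
    if (reg > 0) comp <- comp + reg * fm_sweep(n, e[1], e[2], fs)
    x <- x + amp * comp
  }
  if (profile$noise_sd_c > 0) x <- x + rnorm(n, 0, profile$noise_sd_c)
  if (config$quantization_c > 0) {
    x <- round(x / config$quantization_c) * config$quantization_c
  }
  temp_signal(x, fs_hz = fs, subject_id = profile$name, group = profile$name)
}

#' Default group profiles for the three-group study design
#'
#' The shipped profiles emulate the qualitative group contrasts of the study
#' design: SIRS signals are broadband and irregular across all bands, septic
#' shock signals are dominated by an organized slowly drifting ultradian
#' oscillation with very little measurement noise, and sepsis sits between.
#' Baselines follow the printed group temperature means; amplitudes,
#' regularities and noise levels are free parameters of the generator chosen
#' once as physiologically plausible (see the methods vignette).
#'
#' @return Named list of three [group_profile] objects
#'   (`SIRS`, `sepsis`, `septic_shock`).
#' @export
default_group_profiles <- function() {
  list(
    SIRS = group_profile(
      "SIRS", baseline_c = 38.26, baseline_sd_c = 0.3, trend_c_per_h = 0.01,
      band_amplitudes = c(neurogenic = 0.02, metabolic = 0.06,
                          ultradian = 0.25),
      band_regularity = c(neurogenic = 0.2, metabolic = 0.2,
                          ultradian = 0.1),
      noise_sd_c = 0.01, sofa_range = c(8L, 12L)),
    sepsis = group_profile(
      "sepsis", baseline_c = 38.17, baseline_sd_c = 0.4, trend_c_per_h = 0.02,
      band_amplitudes = c(neurogenic = 0.015, metabolic = 0.05,
                          ultradian = 0.30),
      band_regularity = c(neurogenic = 0.5, metabolic = 0.6,
                          ultradian = 0.7),
      noise_sd_c = 0.007, sofa_range = c(9L, 13L)),
    septic_shock = group_profile(
      "septic_shock", baseline_c = 38.67, baseline_sd_c = 0.3,
      trend_c_per_h = -0.02,
      band_amplitudes = c(neurogenic = 0.01, metabolic = 0.04,
                          ultradian = 0.35),
      band_regularity = c(neurogenic = 0.9, metabolic = 0.9,
                          ultradian = 0.97),
      noise_sd_c = 0.005, sofa_range = c(13L, 18L)))
}

#' Two-group profiles differing only in ultradian-band regularity
#'
#' A controlled construction for parameter-recovery experiments: the two
#' profiles are identical (baseline, trend, noise, amplitudes, neurogenic and
#' metabolic bands, deep-ultradian band) except for the regularity of a
#' 0.00045-0.003 Hz ultradian sub-band, which is irregular (0.1) in the
#' SIRS-like profile and organized (0.9) in the shock-like profile. Any
#' feature that discriminates these cohorts must respond to ultradian-band
#' complexity, not to energy or mean-level differences.
#'
#' @param reg Length-2 numeric: regularity of the contrast band in the
#'   irregular and the regular profile.
#' @return Named list of two [group_profile] objects (`irregular`,
#'   `regular`).
#' @export
recovery_profiles <- function(reg = c(0.1, 0.9)) {
  bands <- list(neurogenic = c(0.025, 0.05),
                metabolic = c(0.00625, 0.025),
                ultradian_mid = c(0.00045, 0.003),
                ultradian_deep = c(0.1 / 2^10, 0.00045))
  mk <- function(name, r) {
    group_profile(
      name, baseline_c = 38.4, baseline_sd_c = 0.3, trend_c_per_h = 0,
      band_amplitudes = c(neurogenic = 0.015, metabolic = 0.05,
                          ultradian_mid = 0.10, ultradian_deep = 0.30),
      band_regularity = c(neurogenic = 0.5, metabolic = 0.5,
                          ultradian_mid = r, ultradian_deep = 0.9),
      noise_sd_c = 0.005, sofa_range = c(8L, 12L), bands = bands)
  }
  list(irregular = mk("irregular", reg[1]), regular = mk("regular", reg[2]))
}

#' Generate a labelled synthetic cohort
#'
#' Draws `n_per_group` subjects from each profile with per-subject seeds
#' derived deterministically from `config$seed`, attaches synthetic SOFA
#' scores drawn uniformly from each profile's `sofa_range`, and (when
#' `config$artifact_rate > 0`) injects a Poisson number of artifact segments
#' per signal.
#'
#' @param profiles List of [group_profile] objects.
#' @param config A [cohort_config].
#' @return List of [temp_signal] objects with `group` and `sofa` set.
#' @export
generate_cohort <- function(profiles, config = cohort_config()) {
  if (length(profiles) == 0) stop("at least one profile is required")
  stopifnot(inherits(config, "cohort_config"))
  npg <- rep_len(config$n_per_group, length(profiles))
  n_total <- sum(npg)
  set.seed(config$seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, 3L * n_total)
  cohort <- vector("list", n_total)
  k <- 0
  for (gi in seq_along(profiles)) {
    prof <- profiles[[gi]]
    for (si in seq_len(npg[gi])) {
      k <- k + 1
      sig <- generate_subject(prof, config, seed = subject_seeds[k])
      sig$subject_id <- sprintf("%s_%02d", prof$name, si)
      set.seed(subject_seeds[n_total + k])
      sig$sofa <- sample(prof$sofa_range[1]:prof$sofa_range[2], 1)
      if (config$artifact_rate > 0) {
        n_seg <- stats::rpois(1, config$artifact_rate)
        if (n_seg > 0) {
          sig <- inject_artifacts(sig, n_seg, config$artifact_max_len_s,
                                  seed = subject_seeds[2 * n_total + k])
        }
      }
      cohort[[k]] <- sig
    }
  }
  cohort
}

#' Inject artifact segments into a signal
#'
#' Corrupts `n_segments` disjoint stretches with either a flat dropout (the
#' sensor sticks at the segment's first value) or a step offset (contact
#' shift), and records the segments in the artifact mask so that
#' [replace_artifacts()] can repair them.
#'
#' @param signal A [temp_signal].
#' @param n_segments Number of segments to inject (>= 0).
#' @param max_len_s Maximum segment length in seconds; must be shorter than a
#'   quarter of the recording.
#' @param seed Integer seed.
#' @return The corrupted [temp_signal] with an updated mask.
#' @export
inject_artifacts <- function(signal, n_segments, max_len_s = 600, seed = 1) {
  stopifnot(inherits(signal, "temp_signal"))
  if (n_segments < 0) stop("n_segments must be >= 0")
  n <- length(signal$samples)
  if (max_len_s >= n / signal$fs_hz / 4) {
    stop("max_len_s must be below a quarter of the recording")
  }
  if (n_segments == 0) return(signal)
  set.seed(seed)
  max_len <- max(2L, floor(max_len_s * signal$fs_hz))
  intervals <- matrix(integer(0), ncol = 2)
  x <- signal$samples
  guard <- 0
  while (nrow(intervals) < n_segments && guard < 1000 * n_segments) {
    guard <- guard + 1
    len <- sample(2:max_len, 1)
    start <- sample.int(n - len, 1)  # 0-based start in [1, n - len]
    cand <- c(start, start + len)
    if (nrow(intervals) == 0 ||
        all(cand[2] <= intervals[, 1] | cand[1] >= intervals[, 2])) {
      idx <- (cand[1] + 1):cand[2]
      if (runif(1) < 0.5) {
        x[idx] <- x[idx[1]]                         # flat dropout
      } else {
        x[idx] <- x[idx] + sample(c(-1, 1), 1) * runif(1, 0.3, 1.5)  # step
      }
      intervals <- rbind(intervals, cand)
    }
  }
  if (nrow(intervals) < n_segments) {
    stop("could not place the requested number of disjoint segments")
  }
  out <- signal
  out$samples <- x
  out$mask <- validate_mask(rbind(signal$mask, intervals), n)
  out
}

#' Write a cohort to per-subject CSV files with a manifest
#'
#' @param cohort List of [temp_signal] objects.
#' @param dir Output directory (created if needed).
#' @return Path of the manifest CSV (columns `subject_id`, `file`,
#'   `mask_file`, `group`, `sofa`), invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(sig) {
    f <- file.path(dir, paste0(sig$subject_id, ".csv"))
    mf <- if (nrow(sig$mask) > 0) {
      file.path(dir, paste0(sig$subject_id, "_mask.csv"))
    } else NA_character_
    write_signal_csv(sig, f, if (!is.na(mf)) mf else NULL)
    data.frame(subject_id = sig$subject_id, file = basename(f),
               mask_file = if (is.na(mf)) "" else basename(mf),
               group = sig$group, sofa = sig$sofa)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a cohort back from a manifest
#'
#' @param manifest_file Path to a manifest CSV written by
#'   [write_cohort_csv()].
#' @param fs_hz Sampling frequency passed to [read_signal_csv()].
#' @return List of [temp_signal] objects.
#' @export
read_cohort_csv <- function(manifest_file, fs_hz = NULL) {
  man <- read.csv(manifest_file, colClasses = "character")
  dir <- dirname(manifest_file)
  lapply(seq_len(nrow(man)), function(i) {
    f <- file.path(dir, man$file[i])
    if (!file.exists(f)) {
      stop(sprintf("manifest: file for subject %s not found: %s",
                   man$subject_id[i], f))
    }
    mf <- if (nzchar(man$mask_file[i])) file.path(dir, man$mask_file[i])
          else NULL
    read_signal_csv(f, mask_file = mf, fs_hz = fs_hz,
                    subject_id = man$subject_id[i], group = man$group[i],
                    sofa = as.numeric(man$sofa[i]))
  })
}
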