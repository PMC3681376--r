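# Meyer filter, DWT/CWT transforms, and the wavelet energy/entropy features.

test_that("the dyadic band map halves frequencies and converts periods to minutes", {
  b <- scale_frequency_bands(1.0, 3)
  expect_equal(b$f_min_hz, c(0.25, 0.125, 0.0625))
  expect_equal(b$f_max_hz, c(0.5, 0.25, 0.125))
  b01 <- scale_frequency_bands(0.1, 9)
  expect_equal(b01$f_min_hz[1], 0.025)
  expect_equal(b01$f_max_hz[1], 0.05)
  expect_equal(b01$period_min_min[1], 1 / 3, tolerance = 1e-12)
  expect_equal(b01$period_max_min[9], 1 / (60 * 0.1 / 2^10),
               tolerance = 1e-12)
  expect_equal(b01$tag, c("neurogenic", "metabolic", "metabolic",
                          rep("ultradian", 6)))
  # bands tile [fs/2^(n+1), fs/2] without overlap
  expect_equal(b01$f_min_hz[-9], b01$f_max_hz[-1])
})

test_that("the generated Meyer filter is orthonormal to truncation accuracy", {
  flt <- meyer_filter()
  h <- flt$h
  L <- length(h)
  expect_equal(L, 102)
  expect_equal(sum(h), sqrt(2), tolerance = 1e-6)
  expect_equal(sum(h^2), 1, tolerance = 1e-8)
  for (k in 1:4) {
    expect_lt(abs(sum(h[seq_len(L - 2 * k)] * h[seq_len(L - 2 * k) +
                                                  2 * k])), 1e-8)
  }
  expect_lt(abs(sum(flt$h * flt$g)), 1e-12)  # QMF orthogonality
})

test_that("the pyramid DWT conserves energy and reports its scales", {
  set.seed(1)
  x <- rnorm(4096)
  dec <- dwt_meyer(x, n_scales = 9, fs_hz = 1)
  expect_length(dec$details, 9)
  expect_equal(vapply(dec$details, length, 1L), 4096 / 2^(1:9))
  total <- sum(vapply(dec$details, function(d) sum(d^2), 1.0)) +
    sum(dec$approx^2)
  expect_equal(total, sum(x^2), tolerance = 1e-6)

  zero <- dwt_meyer(rep(0, 2048), n_scales = 9, fs_hz = 1)
  expect_true(all(vapply(zero$details, function(d) all(d == 0), TRUE)))

  expect_error(dwt_meyer(rnorm(500), n_scales = 9), "1024")
  expect_silent(dwt_meyer(rnorm(8640), n_scales = 9, fs_hz = 0.1))
})

test_that("wavelet energy is the mean squared coefficient and scales quadratically", {
  expect_equal(wavelet_energy(c(0, 0, 0)), 0)
  expect_equal(wavelet_energy(c(3, 4)), 12.5)
  set.seed(2)
  x <- rnorm(2048)
  d1 <- dwt_meyer(x, n_scales = 5, fs_hz = 1)
  d2 <- dwt_meyer(2 * x, n_scales = 5, fs_hz = 1)
  for (s in 1:5) {
    expect_equal(wavelet_energy(d2, s), 4 * wavelet_energy(d1, s),
                 tolerance = 1e-10)
  }
  expect_error(wavelet_energy(numeric(0)), "empty")
})

test_that("wavelet entropy matches hand-computed Shannon values and its bounds", {
  expect_equal(wavelet_entropy(c(0, 0, 5, 0)), 0)
  L <- 16
  expect_equal(wavelet_entropy(rep(2, L)), log(L), tolerance = 1e-12)
  expect_equal(wavelet_entropy(rep(-3, L)), log(L), tolerance = 1e-12)
  expect_equal(wavelet_entropy(c(1, 1, sqrt(2))), 1.5 * log(2),
               tolerance = 1e-12)
  expect_equal(wavelet_entropy(c(1, 1, sqrt(2)), base = "2"), 1.5,
               tolerance = 1e-12)
  expect_warning(h0 <- wavelet_entropy(c(0, 0, 0)), "zero")
  expect_equal(h0, 0)

  # bounds and normalization over random decompositions
  set.seed(3)
  for (rep in 1:5) {
    dec <- dwt_meyer(rnorm(2048), n_scales = 6, fs_hz = 1)
    for (s in 1:6) {
      h <- wavelet_entropy(dec, s)
      expect_gte(h, 0)
      expect_lte(h, log(length(dec$details[[s]])) + 1e-12)
      hn <- wavelet_entropy(dec, s, normalized = TRUE)
      expect_equal(hn, h / log(length(dec$details[[s]])),
                   tolerance = 1e-12)
    }
  }
})

test_that("the CWT map localizes a sinusoid at the right pseudo-frequency", {
  fs <- 0.1
  n <- 8640
  t <- (0:(n - 1)) / fs
  x <- sin(2 * pi * 0.01 * t)
  map <- cwt_meyer(x, fs_hz = fs)
  expect_equal(dim(map), c(64, n))
  row_power <- rowMeans(unclass(map)^2)
  peak_f <- attr(map, "pseudo_freq_hz")[which.max(row_power)]
  expect_gt(peak_f, 0.01 / 1.2)
  expect_lt(peak_f, 0.01 * 1.2)

  zero <- cwt_meyer(rep(0, 2048), fs_hz = 1)
  expect_true(all(unclass(zero) == 0))
  expect_error(cwt_meyer(x, fs_hz = fs, freqs_hz = c(0.01, 0.2)),
               "fs/2")
  expect_error(cwt_meyer(x, fs_hz = fs, freqs_hz = numeric(0)), "empty")
})

test_that("CWT band features follow the entropy conventions per band", {
  fs <- 0.1
  map <- cwt_meyer(rnorm(2048), fs_hz = fs)
  w0 <- capture_warnings(f0 <- cwt_band_features(
    cwt_meyer(rep(0, 2048), fs_hz = fs)))
  expect_match(w0, "zero", all = TRUE)
  expect_equal(unname(f0["CWTen"]), 0)
  expect_equal(unname(f0["CWTentro"]), 0)

  # single nonzero cell inside band 2 gives zero band entropy
  m <- unclass(map) * 0
  freqs <- attr(map, "pseudo_freq_hz")
  row_b2 <- which(freqs > fs / 16 & freqs <= fs / 4)[1]
  m[row_b2, 100] <- 3
  map2 <- structure(m, pseudo_freq_hz = freqs, fs_hz = fs,
                    class = "cwt_map")
  suppressWarnings(f2 <- cwt_band_features(map2))
  expect_equal(unname(f2["CWTentro2"]), 0)
  expect_equal(unname(f2["CWTen2"]),
               9 / (sum(freqs > fs / 16 & freqs <= fs / 4) * 2048))

  # uniform magnitudes in a band: raw entropy log(M), normalized 1
  m3 <- unclass(map) * 0
  rows_b1 <- which(freqs > fs / 4)
  m3[rows_b1, ] <- 1
  map3 <- structure(m3, pseudo_freq_hz = freqs, fs_hz = fs,
                    class = "cwt_map")
  suppressWarnings(f3 <- cwt_band_features(map3))
  expect_equal(unname(f3["CWTentro1_raw"]), log(length(rows_b1) * 2048),
               tolerance = 1e-12)
  expect_equal(unname(f3["CWTentro1"]), 1, tolerance = 1e-12)

  # empty band is an error naming the band
  expect_error(
    cwt_band_features(map, bands = data.frame(band = 1, f_lo_hz = 0.0307,
                                              f_hi_hz = 0.0330)),
    "band 1")
})

test_that("the feature table has one labelled row per subject and variant with no gaps", {
  co <- make_tiny_cohort(n_per_group = 2, seed = 42)
  ft <- extract_feature_table(co, mse_scales = 12)
  expect_equal(nrow(ft), 12)   # 6 subjects x 2 variants
  expect_setequal(unique(ft$variant), c("sign_m", "sign_mdetr"))
  pool <- feature_pool(ft)
  expect_gte(length(pool), 30)
  expect_false(anyNA(ft[, pool]))
  expect_true(all(ft$T_mean > 36 & ft$T_mean < 41))
  # energies and entropies are non-negative
  expect_true(all(ft[, grep("^WE_s", names(ft))] >= 0))
  expect_true(all(ft[, grep("^WEn_s", names(ft))] >= 0))
})
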