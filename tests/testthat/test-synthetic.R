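# Synthetic-cohort generator: determinism, band fidelity, artifact
# injection, and the built-in group contrasts.

quiet_profile <- function(baseline = 37) {
  group_profile("quiet", baseline_c = baseline,
                band_amplitudes = c(neurogenic = 0, metabolic = 0,
                                    ultradian = 0),
                band_regularity = c(neurogenic = 0.5, metabolic = 0.5,
                                    ultradian = 0.5),
                noise_sd_c = 0, baseline_sd_c = 0)
}

single_band_profile <- function(band, reg = 0.3) {
  amps <- c(neurogenic = 0, metabolic = 0, ultradian = 0)
  amps[band] <- 0.5
  group_profile(band, baseline_c = 37, band_amplitudes = amps,
                band_regularity = c(neurogenic = reg, metabolic = reg,
                                    ultradian = reg),
                noise_sd_c = 0, baseline_sd_c = 0)
}

test_that("zero-amplitude profile yields a constant quantized series of the right length", {
  cfg <- cohort_config(duration_s = 86400, fs_hz = 0.1)
  sig <- generate_subject(quiet_profile(), cfg, seed = 1)
  expect_length(sig$samples, 8640)
  expect_true(all(sig$samples == 37.0))
  # trend survives quantization as a staircase but stays near the ramp
  prof_trend <- group_profile("t", baseline_c = 37, trend_c_per_h = 0.1,
                              band_amplitudes = c(neurogenic = 0,
                                                  metabolic = 0,
                                                  ultradian = 0),
                              noise_sd_c = 0, baseline_sd_c = 0)
  sig2 <- generate_subject(prof_trend, cfg, seed = 1)
  expect_equal(sig2$samples[8640] - sig2$samples[1], 2.4, tolerance = 0.05)
})

test_that("generated values live on the quantization grid", {
  cfg <- cohort_config(duration_s = 20480, quantization_c = 0.05)
  sig <- generate_subject(default_group_profiles()$sepsis, cfg, seed = 3)
  expect_true(all(abs(sig$samples / 0.05 -
                        round(sig$samples / 0.05)) < 1e-9))
})

test_that("single-band components concentrate their power in the nominal band", {
  cfg <- cohort_config(duration_s = 86400, quantization_c = 0)
  bands <- physiological_bands(0.1)
  for (b in names(bands)) {
    sig <- generate_subject(single_band_profile(b), cfg, seed = 7)
    x <- sig$samples - mean(sig$samples)
    frac <- periodogram_band_fraction(x, 0.1, bands[[b]][1], bands[[b]][2])
    expect_gt(frac, 0.90)
    peak <- periodogram_peak_freq(x, 0.1)
    expect_gte(peak, bands[[b]][1] * 0.95)
    expect_lte(peak, bands[[b]][2] * 1.05)
  }
})

test_that("invalid configurations and profiles are rejected", {
  expect_error(cohort_config(duration_s = -1), "positive")
  expect_error(cohort_config(duration_s = 100, fs_hz = 0.1), "2\\^10")
  expect_error(group_profile("bad", baseline_c = 30), "35")
  expect_error(group_profile("bad",
                             band_amplitudes = c(neurogenic = -1,
                                                 metabolic = 0,
                                                 ultradian = 0)), ">= 0")
  expect_error(group_profile("bad",
                             band_regularity = c(neurogenic = 2,
                                                 metabolic = 0,
                                                 ultradian = 0)), "0, 1")
})

test_that("cohort generation is labelled, sized and deterministic, with ordered SOFA", {
  cfg <- cohort_config(n_per_group = 2, duration_s = 20480, seed = 5)
  co <- generate_cohort(default_group_profiles(), cfg)
  expect_length(co, 6)
  expect_equal(table(vapply(co, function(s) s$group, ""))[
    c("SIRS", "sepsis", "septic_shock")],
    table(rep(c("SIRS", "sepsis", "septic_shock"), each = 2))[
      c("SIRS", "sepsis", "septic_shock")])
  co2 <- generate_cohort(default_group_profiles(), cfg)
  expect_identical(lapply(co, `[[`, "samples"), lapply(co2, `[[`, "samples"))
  expect_error(generate_cohort(list(), cfg), "at least one profile")

  # SOFA ordering holds on a larger draw
  cfg2 <- cohort_config(n_per_group = 15, duration_s = 20480, seed = 8)
  co3 <- generate_cohort(default_group_profiles()[c("SIRS", "septic_shock")],
                         cfg2)
  sofa <- vapply(co3, function(s) s$sofa, 1.0)
  grp <- vapply(co3, function(s) s$group, "")
  expect_gt(median(sofa[grp == "septic_shock"]), median(sofa[grp == "SIRS"]))
})

test_that("artifact injection records disjoint in-bounds segments and repair helps", {
  cfg <- cohort_config(duration_s = 20480, seed = 2)
  clean <- generate_subject(default_group_profiles()$SIRS, cfg, seed = 2)

  expect_identical(inject_artifacts(clean, 0, 600, seed = 1), clean)
  expect_error(inject_artifacts(clean, -1, 600), ">= 0")
  expect_error(inject_artifacts(clean, 1, 6000), "quarter")

  corrupted <- inject_artifacts(clean, 3, 600, seed = 9)
  m <- corrupted$mask
  expect_equal(nrow(m), 3)
  expect_true(all(m[, 1] < m[, 2]))
  expect_true(all(m[, 1] >= 0 & m[, 2] <= length(clean$samples)))
  if (nrow(m) > 1) expect_true(all(m[-1, 1] >= m[-nrow(m), 2]))

  repaired <- replace_artifacts(corrupted)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(repaired$samples, clean$samples),
            rmse(corrupted$samples, clean$samples))
})

test_that("default profiles produce higher mid-scale wavelet entropy in SIRS than shock", {
  cfg <- cohort_config(n_per_group = 5, duration_s = 86400, seed = 21)
  co <- generate_cohort(default_group_profiles()[c("SIRS", "septic_shock")],
                        cfg)
  wen46 <- vapply(co, function(sig) {
    pp <- preprocess_signal(sig)
    dec <- dwt_meyer(pp$sign_mdetr)
    median(vapply(4:6, function(s) wavelet_entropy(dec, s), 1.0))
  }, 1.0)
  grp <- vapply(co, function(s) s$group, "")
  expect_gt(median(wen46[grp == "SIRS"]),
            median(wen46[grp == "septic_shock"]))
})

test_that("cohorts round-trip through per-subject CSV files and a manifest", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_per_group = 1, duration_s = 20480, seed = 4,
                       artifact_rate = 2)
  co <- generate_cohort(default_group_profiles()[1:2], cfg)
  manifest <- write_cohort_csv(co, dir)
  back <- read_cohort_csv(manifest)
  expect_length(back, 2)
  expect_equal(back[[1]]$samples, co[[1]]$samples, tolerance = 1e-12)
  expect_equal(back[[1]]$group, co[[1]]$group)
  expect_equal(back[[1]]$sofa, co[[1]]$sofa)
  expect_equal(nrow(back[[1]]$mask), nrow(co[[1]]$mask))
})
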