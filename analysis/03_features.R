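#!/usr/bin/env Rscript
# Extract the full feature table: per subject and preprocessing variant the
# 18 DWT features (wavelet energy and entropy at 9 dyadic scales), the 10
# CWT band features, multiscale entropy summaries (SampEn, sumEn over 36
# coarse-graining factors) and the raw-signal mean and SD.

library(thermentropy)

cohort <- read_cohort_csv("scratch/cohort/manifest.csv")
ft <- extract_feature_table(cohort)
write_feature_table(ft, "results/feature_table.csv")

# the dyadic scale-to-frequency map the DWT features live on
write.csv(scale_frequency_bands(0.1, 9), "results/band_map.csv",
          row.names = FALSE)

# one full MSE curve per group, for inspection
per_group <- cohort[!duplicated(vapply(cohort, function(s) s$group, ""))]
curves <- do.call(rbind, lapply(per_group, function(sig) {
  res <- mse_curve(preprocess_signal(sig)$sign_mdetr$samples)
  cbind(subject_id = sig$subject_id, group = sig$group, res$curve)
}))
write.csv(curves, "results/mse_curves_example.csv", row.names = FALSE)

cat("Feature table:", nrow(ft), "rows x", length(feature_pool(ft)),
    "candidate features\n")
med <- aggregate(ft[ft$variant == "sign_mdetr",
                    c("WEn_s5", "CWTentro3", "sumEn")],
                 by = list(group = ft$group[ft$variant == "sign_mdetr"]),
                 median)
cat("group medians (sign_mdetr):\n")
print(med, digits = 3)
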