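#!/usr/bin/env Rscript
# Univariate statistics over the feature table: normality screening
# (Lilliefors), per-feature group comparison (pairwise rank-sum +
# Kruskal-Wallis), Dunn/Bonferroni follow-up for selected features, and
# Spearman correlations against the SOFA severity score.

library(thermentropy)

ft <- read_feature_table("results/feature_table.csv")

# normality of the demographic-style variables on the whole cohort
raw <- ft[ft$variant == "sign_m", ]
lt <- lilliefors_test(raw$T_mean, b = 2000, seed = 1)
cat(sprintf("Lilliefors on mean temperature: D = %.3f, p = %.3f -> %s\n",
            lt$statistic, lt$p_value,
            ifelse(lt$p_value > 0.05, "compatible with normality (ANOVA)",
                   "non-normal (rank tests)")))
av <- anova_oneway(raw$T_mean, raw$group)
cat(sprintf("one-way ANOVA on mean temperature: F = %.2f, p = %.3f\n",
            av$f, av$p_value))

tab <- group_stats_table(ft)
write.csv(tab, "results/group_stats.csv", row.names = FALSE)
sig <- tab[tab$p_kw < 0.05, c("feature", "variant", "p_kw")]
cat("\nfeatures with Kruskal-Wallis p < 0.05:\n")
print(sig[order(sig$p_kw), ], row.names = FALSE, digits = 3)

# Dunn/Bonferroni follow-up for the strongest feature
if (nrow(sig)) {
  best <- sig$feature[which.min(sig$p_kw)]
  bestv <- sig$variant[which.min(sig$p_kw)]
  sub <- ft[ft$variant == bestv, ]
  cat(sprintf("\nDunn/Bonferroni pairs for %s (%s):\n", best, bestv))
  print(kw_multiple_comparison(sub[[best]], sub$group), digits = 3)
}

# severity correlations (sign_mdetr variant)
det <- ft[ft$variant == "sign_mdetr", ]
rows <- lapply(c("WEn_s6", "WEn_s8", "sumEn", "CWTen"), function(f) {
  s <- spearman_vs_severity(det[[f]], det$sofa)
  data.frame(feature = f, rho = s$rho, p = s$p_value)
})
sofa_tab <- do.call(rbind, rows)
write.csv(sofa_tab, "results/sofa_correlations.csv", row.names = FALSE)
cat("\nSpearman rho against SOFA (sign_mdetr):\n")
print(sofa_tab, row.names = FALSE, digits = 3)
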