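#!/usr/bin/env Rscript
# Unsupervised structure: euclidean dissimilarity over predefined feature
# subsets, 2-cluster k-means, intraclass/interclass distances, clustering
# cost, and agreement with the SIRS-versus-infected partition.

library(thermentropy)

ft <- read_feature_table("results/feature_table.csv")
det <- ft[ft$variant == "sign_mdetr", ]

tab <- evaluate_clusterings(det, seed = 1)
write.csv(tab, "results/clustering.csv", row.names = FALSE)

cat("Clustering evaluation (sign_mdetr), ordered by cost:\n")
print(tab, row.names = FALSE, digits = 3)

cat(sprintf(
  "\nMost compact clusters: %s (cost %.2f, accuracy %.1f%% vs SIRS/infected)\n",
  tab$subset[1], tab$cost[1], tab$accuracy[1]))
best <- tab$subset[which.max(tab$accuracy)]
cat(sprintf("Best class agreement: %s (accuracy %.1f%%)\n",
            best, max(tab$accuracy)))

# export the dissimilarity matrix of the best-agreement subset
dm <- pairwise_distance_matrix(det, cluster_feature_subsets()[[best]])
write.csv(as.data.frame(unclass(dm)), "results/dissimilarity_best.csv")
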