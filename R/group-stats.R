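# Univariate statistical battery over the feature table: normality
# screening, pairwise rank-sum tests, Kruskal-Wallis with Dunn/Bonferroni
# follow-up, Spearman correlation against severity, and one-way ANOVA for
# the normally distributed demographics.

#' Lilliefors test of composite normality
#'
#' Kolmogorov-Smirnov statistic against a normal distribution with mean and
#' SD estimated from the data. Because parameters are estimated, the
#' classical KS null is invalid; the p-value is obtained from a seeded
#' Monte-Carlo null of `b` Gaussian samples of the same size.
#'
#' @param x Numeric vector, n >= 4, non-constant.
#' @param b Number of Monte-Carlo null replicates.
#' @param seed Seed for the null simulation.
#' @return List with `statistic` (D) and `p_value`.
#' @export
lilliefors_test <- function(x, b = 10000, seed = 1) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4) stop("lilliefors test needs n >= 4")
  if (sd(x) == 0) stop("constant input")
  d_obs <- lilliefors_stat(x)
  set.seed(seed)
  exceed <- 0L
  done <- 0L
  chunk <- max(1L, min(b, floor(2e6 / n)))
  while (done < b) {
    k <- min(chunk, b - done)
    z <- matrix(rnorm(k * n), nrow = k)
    d_null <- apply(z, 1, lilliefors_stat)
    exceed <- exceed + sum(d_null >= d_obs)
    done <- done + k
  }
  list(statistic = d_obs, p_value = (exceed + 1) / (b + 1))
}

lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  p <- pnorm(z)
  max(seq_len(n) / n - p, p - (seq_len(n) - 1) / n)
}

# Split values by label into a list of >= 2 groups, preserving label order
# of first appearance.
split_groups <- function(values, labels) {
  labels <- as.character(labels)
  groups <- split(values, factor(labels, levels = unique(labels)))
  if (any(vapply(groups, length, 1L) == 0)) stop("empty group")
  groups
}

#' Pairwise Wilcoxon rank-sum tests
#'
#' Two-sided rank-sum test for every pair of groups. The exact null
#' distribution is enumerated when the combined sample size is at most 20
#' and there are no ties; otherwise the normal approximation with tie
#' correction is used.
#'
#' @param values Numeric vector.
#' @param labels Group labels (>= 2 observations per group).
#' @return Named numeric vector of p-values, one per group pair, named
#'   `p_<i>_<j>` in order of label appearance.
#' @export
ranksum_pairwise <- function(values, labels) {
  groups <- split_groups(values, labels)
  if (any(vapply(groups, length, 1L) < 2)) {
    stop("each group needs at least 2 observations")
  }
  k <- length(groups)
  out <- c()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      a <- groups[[i]]; bb <- groups[[j]]
      exact <- (length(a) + length(bb) <= 20) &&
        !anyDuplicated(c(a, bb))
      p <- suppressWarnings(
        wilcox.test(a, bb, exact = exact, correct = TRUE)$p.value)
      out[sprintf("p_%d_%d", i, j)] <- p
    }
  }
  out
}

#' Kruskal-Wallis test with per-group mean ranks
#'
#' Tie-corrected H statistic with a chi-square reference on `k - 1` degrees
#' of freedom, plus the per-group mean ranks used by the multiple-comparison
#' follow-up.
#'
#' @inheritParams ranksum_pairwise
#' @return List with `h`, `p_value`, `df` and `mean_ranks`.
#' @export
kruskal_wallis <- function(values, labels) {
  groups <- split_groups(values, labels)
  if (length(groups) < 2) stop("at least 2 groups are required")
  kt <- kruskal.test(values, factor(as.character(labels),
                                    levels = names(groups)))
  rk <- rank(values)
  mean_ranks <- vapply(split(rk, factor(as.character(labels),
                                        levels = names(groups))), mean, 1.0)
  list(h = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter), mean_ranks = mean_ranks)
}

#' Dunn-type multiple comparison after Kruskal-Wallis
#'
#' Pairwise comparison of mean ranks with the tie-corrected normal standard
#' error and Bonferroni adjustment over the pairs.
#'
#' @inheritParams ranksum_pairwise
#' @param alpha Family-wise significance level.
#' @return Data frame with one row per pair: `group_i`, `group_j`,
#'   `diff_mean_rank`, `z`, `p`, `p_adj`, `significant`.
#' @export
kw_multiple_comparison <- function(values, labels, alpha = 0.05) {
  groups <- split_groups(values, labels)
  k <- length(groups)
  n <- length(values)
  rk <- rank(values)
  fac <- factor(as.character(labels), levels = names(groups))
  mean_ranks <- vapply(split(rk, fac), mean, 1.0)
  sizes <- vapply(groups, length, 1L)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties)
  var_base <- n * (n + 1) / 12 - tie_term / (12 * (n - 1))
  n_pairs <- k * (k - 1) / 2
  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt(var_base * (1 / sizes[i] + 1 / sizes[j]))
      z <- (mean_ranks[i] - mean_ranks[j]) / se
      p <- 2 * pnorm(-abs(z))
      rows[[length(rows) + 1]] <- data.frame(
        group_i = names(groups)[i], group_j = names(groups)[j],
        diff_mean_rank = unname(mean_ranks[i] - mean_ranks[j]),
        z = unname(z), p = p, p_adj = min(1, n_pairs * p))
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p_adj < alpha
  out
}

#' Spearman rank correlation against a severity score
#'
#' Tie-corrected Spearman rho with its asymptotic p-value.
#'
#' @param feature Numeric vector.
#' @param sofa Numeric vector of the same length (e.g. SOFA scores).
#' @return List with `rho` and `p_value`.
#' @export
spearman_vs_severity <- function(feature, sofa) {
  if (length(feature) != length(sofa)) stop("lengths differ")
  ok <- complete.cases(feature, sofa)
  if (sum(ok) < 4) stop("need at least 4 complete pairs")
  if (sd(feature[ok]) == 0 || sd(sofa[ok]) == 0) stop("constant input")
  ct <- suppressWarnings(cor.test(feature[ok], sofa[ok],
                                  method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' One-way analysis of variance
#'
#' Classical equal-variance one-way ANOVA, used for the normally
#' distributed variables (age, mean temperature).
#'
#' @inheritParams ranksum_pairwise
#' @return List with `f`, `p_value`, `df_between`, `df_within`.
#' @export
anova_oneway <- function(values, labels) {
  groups <- split_groups(values, labels)
  k <- length(groups)
  n <- length(values)
  grand <- mean(values)
  ss_between <- sum(vapply(groups, function(g)
    length(g) * (mean(g) - grand)^2, 1.0))
  ss_within <- sum(vapply(groups, function(g)
    sum((g - mean(g))^2), 1.0))
  df1 <- k - 1
  df2 <- n - k
  f <- (ss_between / df1) / (ss_within / df2)
  list(f = f, p_value = pf(f, df1, df2, lower.tail = FALSE),
       df_between = df1, df_within = df2)
}

#' Group-comparison summary over a feature table
#'
#' For each feature and preprocessing variant: per-group
#' `median (25th-75th)` summaries, pairwise rank-sum p-values, and the
#' Kruskal-Wallis p-value.
#'
#' @param feature_table Data frame from [extract_feature_table()].
#' @param features Feature columns to summarize (default: the canonical
#'   pool from [feature_pool()]).
#' @return Data frame with one row per feature x variant.
#' @export
group_stats_table <- function(feature_table, features = NULL) {
  if (is.null(features)) features <- feature_pool(feature_table)
  variants <- unique(feature_table$variant)
  groups <- unique(feature_table$group)
  rows <- list()
  for (v in variants) {
    sub <- feature_table[feature_table$variant == v, ]
    for (f in features) {
      vals <- sub[[f]]
      med <- vapply(groups, function(g) {
        x <- vals[sub$group == g]
        sprintf("%.3g (%.3g-%.3g)", median(x), quantile(x, 0.25),
                quantile(x, 0.75))
      }, "")
      p_pair <- ranksum_pairwise(vals, sub$group)
      kw <- kruskal_wallis(vals, sub$group)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(feature = f, variant = v),
        as.data.frame(as.list(setNames(med, paste0("median_", groups)))),
        as.data.frame(as.list(p_pair)),
        data.frame(p_kw = kw$p_value))
    }
  }
  do.call(rbind, rows)
}
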