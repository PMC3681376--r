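# Nonparametric battery: Lilliefors, rank-sum, Kruskal-Wallis with Dunn
# follow-up, Spearman, ANOVA.

test_that("the Monte-Carlo Lilliefors test is calibrated and powered", {
  set.seed(4)
  p_norm <- replicate(60, lilliefors_test(rnorm(500), b = 400,
                                          seed = sample.int(1e6, 1))$p_value)
  expect_gte(mean(p_norm > 0.05), 0.95)
  p_exp <- replicate(40, lilliefors_test(rexp(500), b = 400,
                                         seed = sample.int(1e6, 1))$p_value)
  expect_gte(mean(p_exp < 0.05), 0.90)
  expect_error(lilliefors_test(c(1, 2, 3)), "n >= 4")
  expect_error(lilliefors_test(rep(2, 10)), "constant")
})

test_that("the Monte-Carlo Lilliefors p agrees with the analytic approximation", {
  skip_if_not_installed("nortest")
  set.seed(8)
  x <- rnorm(200) + 0.3 * rexp(200)
  p_mc <- lilliefors_test(x, b = 4000, seed = 1)$p_value
  p_ref <- nortest::lillie.test(x)$p.value
  expect_lt(abs(p_mc - p_ref), 0.05)
})

test_that("pairwise rank-sum p-values match exact enumeration and are rank-based", {
  p <- ranksum_pairwise(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(unname(p["p_1_2"]), 0.1, tolerance = 1e-12)
  expect_equal(unname(p["p_1_2"]),
               ranksum_exact_enum(c(1, 2, 3), c(4, 5, 6)))

  set.seed(6)
  a <- rnorm(7); b <- rnorm(6) + 0.5
  p2 <- ranksum_pairwise(c(a, b), rep(c("a", "b"), c(7, 6)))
  expect_equal(unname(p2["p_1_2"]), ranksum_exact_enum(a, b),
               tolerance = 1e-12)

  # identical groups: p in the top region
  p3 <- ranksum_pairwise(c(1:5, 1:5), rep(c("a", "b"), each = 5))
  expect_gte(unname(p3["p_1_2"]), 0.99)

  # within-group reordering leaves p unchanged
  v <- c(rnorm(8), rnorm(9))
  l <- rep(c("x", "y"), c(8, 9))
  expect_equal(ranksum_pairwise(v, l),
               ranksum_pairwise(c(v[8:1], v[17:9]), l))
  expect_error(ranksum_pairwise(c(1, 2, 3), c("a", "a", "b")),
               "at least 2")
})

test_that("Kruskal-Wallis reproduces the exact rank computation and is monotone-invariant", {
  v <- c(1, 2, 3, 4, 5, 6)
  l <- rep(c("g1", "g2", "g3"), each = 2)
  kw <- kruskal_wallis(v, l)
  # exact hand computation: mean ranks 1.5, 3.5, 5.5 -> H = 32/7
  expect_equal(kw$h, 32 / 7, tolerance = 1e-12)
  expect_equal(kw$p_value, pchisq(32 / 7, 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(unname(kw$mean_ranks), c(1.5, 3.5, 5.5))

  kw2 <- kruskal_wallis(exp(v), l)   # strictly monotone transform
  expect_equal(kw2$h, kw$h)

  same <- kruskal_wallis(rep(c(3, 1, 2), 3), rep(c("a", "b", "c"), each = 3))
  expect_lt(same$h, 1e-9)
  expect_gt(same$p_value, 0.999)
})

test_that("Dunn comparisons flag exactly the separated pairs, monotonically in alpha", {
  v <- c(1:5, 11:15, 21:25)
  l <- rep(c("g1", "g2", "g3"), each = 5)
  mc <- kw_multiple_comparison(v, l, alpha = 0.05)
  # mean ranks 3, 8, 13; se = sqrt(20 * 2/5) = 2.828; z13 = 3.536
  expect_equal(mc$z[mc$group_i == "g1" & mc$group_j == "g3"],
               -10 / sqrt(8), tolerance = 1e-9)
  expect_identical(mc$significant, c(FALSE, TRUE, FALSE))

  mc_loose <- kw_multiple_comparison(v, l, alpha = 0.3)
  expect_true(all(mc$significant <= mc_loose$significant))

  none <- kw_multiple_comparison(rep(c(5, 6, 7), 3),
                                 rep(c("a", "b", "c"), each = 3))
  expect_false(any(none$significant))
})

test_that("Spearman correlation handles monotone, reversed and tied inputs", {
  expect_equal(spearman_vs_severity(1:6, (1:6)^3)$rho, 1)
  expect_equal(spearman_vs_severity(1:6, -(1:6))$rho, -1)
  # hand computation: d^2 sums to 8 -> rho = 1 - 48/120
  r <- spearman_vs_severity(c(1, 2, 3, 4, 5), c(3, 1, 2, 5, 4))
  expect_equal(r$rho, 0.6, tolerance = 1e-12)
  ct <- suppressWarnings(cor.test(c(1, 2, 3, 4, 5), c(3, 1, 2, 5, 4),
                                  method = "spearman"))
  expect_equal(r$rho, unname(ct$estimate))
  expect_error(spearman_vs_severity(1:5, 1:4), "lengths")
  expect_error(spearman_vs_severity(rep(1, 5), 1:5), "constant")
})

test_that("one-way ANOVA matches the sum-of-squares decomposition and lm", {
  v <- c(2, 3, 4, 6, 7, 8, 11, 12, 16)
  l <- rep(c("a", "b", "c"), each = 3)
  res <- anova_oneway(v, l)
  ref <- anova(lm(v ~ l))
  expect_equal(res$f, ref$`F value`[1], tolerance = 1e-12)
  expect_equal(res$p_value, ref$`Pr(>F)`[1], tolerance = 1e-12)

  same <- anova_oneway(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_lt(same$f, 1e-9)

  # equal means, unequal variances: no systematic rejection
  set.seed(9)
  ps <- replicate(20, {
    anova_oneway(c(rnorm(10, sd = 1), rnorm(10, sd = 3), rnorm(10, sd = 5)),
                 rep(c("a", "b", "c"), each = 10))$p_value
  })
  expect_gt(median(ps), 0.2)
})

test_that("the group summary table reports medians with quartiles and all p-values", {
  set.seed(10)
  ft <- data.frame(
    subject_id = sprintf("s%02d", 1:30),
    group = rep(c("SIRS", "sepsis", "septic_shock"), each = 10),
    variant = "sign_mdetr",
    feat_a = c(rnorm(10, 5), rnorm(10, 3), rnorm(10, 1)),
    feat_b = rnorm(30))
  tab <- group_stats_table(ft, features = c("feat_a", "feat_b"))
  expect_equal(nrow(tab), 2)
  expect_true(all(c("median_SIRS", "p_1_2", "p_1_3", "p_2_3", "p_kw") %in%
                    names(tab)))
  expect_lt(tab$p_kw[tab$feature == "feat_a"], 0.01)
  expect_gt(tab$p_kw[tab$feature == "feat_b"], 0.05)
  expect_match(tab$median_SIRS[1], "^-?[0-9.]+ \\(-?[0-9.]+--?[0-9.]+\\)$")
})
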