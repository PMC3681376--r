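# LDA, leave-one-out evaluation, and the random-subset wrapper.

make_blobs <- function(n = 15, sep = 6, p = 2, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n * p, 0, 1), ncol = p),
             matrix(rnorm(n * p, sep, 1), ncol = p))
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = rep(c("a", "b"), each = n))
}

test_that("the linear discriminant places symmetric classes at the midpoint", {
  set.seed(20)
  x <- matrix(c(rnorm(50, -1), rnorm(50, 1)), ncol = 1,
              dimnames = list(NULL, "f1"))
  y <- rep(c("lo", "hi"), each = 50)
  fit <- lda_fit(x, y)
  boundary <- fit$threshold / fit$w
  expect_lt(abs(boundary), 0.25)

  # swapping labels flips every prediction
  fit2 <- lda_fit(x, rev(y))
  grid <- matrix(seq(-3, 3, 0.5), ncol = 1, dimnames = list(NULL, "f1"))
  p1 <- predict(fit, grid)
  p2 <- predict(fit2, grid)
  expect_true(all((p1 == "lo") == (p2 == "hi")))

  blobs <- make_blobs()
  fitb <- lda_fit(blobs$X, blobs$y)
  expect_equal(unname(predict(fitb, blobs$X)), blobs$y)

  expect_error(lda_fit(x, rep("one", 100)), "two classes")
  expect_error(lda_fit(x[1:3, , drop = FALSE], c("a", "a", "b")),
               "at least 2")
})

test_that("the discriminant agrees with the reference implementation on balanced data", {
  skip_if_not_installed("MASS")
  blobs <- make_blobs(n = 25, sep = 2.5, p = 3, seed = 21)
  fit <- lda_fit(blobs$X, blobs$y)
  ref <- MASS::lda(blobs$X, grouping = blobs$y, prior = c(0.5, 0.5))
  expect_equal(unname(predict(fit, blobs$X)),
               as.character(predict(ref, blobs$X)$class))
})

test_that("shrinkage keeps singular covariances workable", {
  # p > n - 2: pooled covariance is singular
  set.seed(22)
  X <- matrix(rnorm(6 * 8), nrow = 6, dimnames = list(NULL, paste0("f", 1:8)))
  y <- rep(c("a", "b"), each = 3)
  fit <- lda_fit(X, y)
  expect_true(all(is.finite(fit$w)))
  expect_length(predict(fit, X), 6)
})

test_that("leave-one-out metrics come from pooled confusion counts", {
  blobs <- make_blobs(n = 10, sep = 8, seed = 23)
  res <- loocv_evaluate(blobs$X, blobs$y)
  expect_equal(res$accuracy, 100)
  expect_equal(res$sensitivity, 100)
  expect_equal(res$specificity, 100)
  expect_equal(res$balanced_accuracy, 100)
  expect_length(res$predictions, 20)
  expect_equal(res$tp + res$tn + res$fp + res$fn, 20)
  expect_error(loocv_evaluate(blobs$X[1:3, ], blobs$y[1:3]), "at least 4")
})

test_that("classification metrics reconstruct accuracy from sensitivity and specificity", {
  # 5 SIRS all correct, 9 of 10 sepsis correct (positive class SIRS)
  truth <- rep(c("SIRS", "sepsis"), c(5, 10))
  pred <- c(rep("SIRS", 5), "SIRS", rep("sepsis", 9))
  m <- classification_metrics(pred, truth, positive = "SIRS")
  expect_equal(m$accuracy, 100 * 14 / 15, tolerance = 1e-12)
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 90)

  # 4 of 5 SIRS and all 7 shock correct
  truth2 <- rep(c("SIRS", "septic_shock"), c(5, 7))
  pred2 <- c(rep("SIRS", 4), "septic_shock", rep("septic_shock", 7))
  m2 <- classification_metrics(pred2, truth2, positive = "SIRS")
  expect_equal(m2$accuracy, 100 * 11 / 12, tolerance = 1e-12)
  expect_equal(m2$sensitivity, 80)
  expect_equal(m2$specificity, 100)
})

test_that("the wrapper's fast scorer equals the reporting LOOCV path", {
  set.seed(30)
  for (i in 1:10) {
    n <- sample(c(10, 14, 18), 1)
    p <- sample(1:4, 1)
    X <- matrix(rnorm(2 * n * p, rep(c(0, 1.5), each = n)), ncol = p)
    colnames(X) <- paste0("f", seq_len(p))
    y <- rep(c("a", "b"), each = n)
    res <- loocv_evaluate(X, y)
    fast <- thermentropy:::loocv_balacc(X, y == res$positive)
    expect_equal(100 * fast, res$balanced_accuracy, tolerance = 1e-12)
  }
})

test_that("the wrapper concentrates its index on the informative feature", {
  set.seed(24)
  n <- 14
  ft <- data.frame(good = c(rnorm(n, 0, 0.5), rnorm(n, 5, 0.5)),
                   junk1 = rnorm(2 * n), junk2 = rnorm(2 * n),
                   junk3 = rnorm(2 * n), junk4 = rnorm(2 * n),
                   junk5 = rnorm(2 * n))
  y <- rep(c("a", "b"), each = n)
  cfg <- wrapper_config(subset_size = 3, n_iterations = 150, seed = 5)
  wr <- wrapper_select(as.matrix(ft), labels = y, config = cfg)
  expect_equal(names(wr$significance_index)[1], "good")
  expect_true("good" %in% wr$randset)
  expect_gt(nrow(wr$successful), 0)

  # determinism
  wr2 <- wrapper_select(as.matrix(ft), labels = y, config = cfg)
  expect_identical(wr$significance_index, wr2$significance_index)
  expect_identical(wr$randset, wr2$randset)

  # unattainable threshold: nothing succeeds
  cfg2 <- wrapper_config(subset_size = 3, n_iterations = 50,
                         success_threshold = 1.01, seed = 5)
  wr3 <- wrapper_select(as.matrix(ft), labels = y, config = cfg2)
  expect_equal(nrow(wr3$successful), 0)
  expect_length(wr3$randset, 0)

  expect_error(wrapper_config(success_threshold = 0.4), "0.5")
  expect_error(wrapper_select(as.matrix(ft), labels = y,
                              config = wrapper_config(subset_size = 10),
                              pool = names(ft)), "pool")
})

test_that("pairwise classification covers every pair and variant", {
  set.seed(25)
  n <- 8
  mk <- function(g, v, shift) {
    data.frame(subject_id = sprintf("%s%02d", g, 1:n), group = g,
               variant = v,
               WEn_s5 = rnorm(n, shift), WEn_s6 = rnorm(n, shift),
               T_mean = rnorm(n, 38), T_sd = abs(rnorm(n, 0.3, 0.05)))
  }
  ft <- rbind(mk("SIRS", "sign_m", 4), mk("sepsis", "sign_m", 2),
              mk("septic_shock", "sign_m", 0),
              mk("SIRS", "sign_mdetr", 4), mk("sepsis", "sign_mdetr", 2),
              mk("septic_shock", "sign_mdetr", 0))
  cfg <- wrapper_config(subset_size = 2, n_iterations = 40, seed = 6)
  tab <- pairwise_classify(ft, config = cfg,
                           pool = c("WEn_s5", "WEn_s6", "T_mean", "T_sd"))
  expect_equal(nrow(tab), 6)            # 3 pairs x 2 variants
  expect_setequal(unique(tab$pair),
                  c("SIRS vs sepsis", "SIRS vs septic_shock",
                    "sepsis vs septic_shock"))
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 100))
  # the well-separated pair classifies nearly perfectly
  expect_gte(min(tab$balanced_accuracy[tab$pair == "SIRS vs septic_shock"]),
             90)
})

test_that("single-feature subsets reproduce univariate evaluation", {
  blobs <- make_blobs(n = 12, sep = 3, seed = 26)
  uni <- loocv_evaluate(blobs$X, blobs$y, subset = "f1")
  expect_equal(uni$subset, "f1")
  cfg <- wrapper_config(subset_size = 1, n_iterations = 30, seed = 7)
  wr <- wrapper_select(blobs$X, labels = blobs$y, config = cfg)
  expect_true(all(nchar(wr$successful$subset) == 2))  # single features
})
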