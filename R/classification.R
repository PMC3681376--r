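# Supervised stage: linear discriminant analysis, leave-one-out
# cross-validation, and random-subset wrapper feature selection scored by
# balanced accuracy.

#' Fit a two-class linear discriminant
#'
#' The linear boundary is built from the class means and the pooled
#' within-class covariance; when the covariance is (near-)singular -- the
#' usual case with few subjects and several features -- a shrinkage ridge
#' `lambda = 1e-3 * trace(S)/p` is added to the diagonal. Classes get equal
#' prior weight: the decision threshold is the projection midpoint between
#' the class means.
#'
#' @param x Numeric matrix (subjects x features).
#' @param y Class labels with exactly two levels, each with >= 2 samples.
#' @return An object of class `lda_model` with the projection vector,
#'   threshold and class labels.
#' @export
lda_fit <- function(x, y) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing values in predictors")
  y <- as.character(y)
  classes <- unique(y)
  if (length(classes) != 2) stop("exactly two classes are required")
  if (any(table(y) < 2)) stop("each class needs at least 2 samples")
  x0 <- x[y == classes[1], , drop = FALSE]
  x1 <- x[y == classes[2], , drop = FALSE]
  m0 <- colMeans(x0)
  m1 <- colMeans(x1)
  c0 <- sweep(x0, 2, m0)
  c1 <- sweep(x1, 2, m1)
  s <- (crossprod(c0) + crossprod(c1)) / (nrow(x) - 2)
  # solve via Cholesky; a failure signals (near-)singularity, handled by a
  # shrinkage ridge
  w <- tryCatch(drop(chol2inv(chol(s)) %*% (m1 - m0)),
                error = function(e) NULL)
  if (is.null(w) || !all(is.finite(w))) {
    lambda <- 1e-3 * sum(diag(s)) / ncol(s)
    if (lambda <= 0) lambda <- 1e-8
    w <- drop(solve(s + diag(lambda, ncol(s)), m1 - m0))
  }
  structure(list(w = as.numeric(w), threshold = sum(w * (m0 + m1)) / 2,
                 classes = classes, features = colnames(x)),
            class = "lda_model")
}

#' @param object An `lda_model`.
#' @param newdata Numeric matrix with the model's feature columns.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @rdname lda_fit
#' @export
predict.lda_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  score <- drop(newdata %*% object$w)
  ifelse(score > object$threshold, object$classes[2], object$classes[1])
}

#' Leave-one-out evaluation of an LDA feature subset
#'
#' Each subject in turn is held out, the discriminant is refit on the rest,
#' and the held-out prediction is recorded. Metrics come from the pooled
#' confusion counts. Folds whose training set degenerates to a single class
#' are recorded as failed and predicted as the majority class.
#'
#' @param feature_table Feature table (one variant) or a numeric matrix.
#' @param labels Two-class labels (taken from `feature_table$group` when
#'   omitted and the table has a `group` column).
#' @param subset Feature columns to use.
#' @param positive Label treated as positive for sensitivity (default:
#'   `"SIRS"` when present, otherwise the first class).
#' @return An object of class `classification_result`: accuracy,
#'   sensitivity, specificity, balanced accuracy (all percent), per-fold
#'   predictions, confusion counts and the subset.
#' @export
loocv_evaluate <- function(feature_table, labels = NULL, subset = NULL,
                           positive = NULL) {
  X <- feature_matrix(feature_table, subset)
  if (is.null(labels)) {
    if (is.data.frame(feature_table) && !is.null(feature_table$group)) {
      labels <- feature_table$group
    } else stop("labels are required")
  }
  y <- as.character(labels)
  n <- nrow(X)
  if (n < 4) stop("need at least 4 subjects")
  classes <- unique(y)
  if (length(classes) != 2) stop("exactly two classes are required")
  if (is.null(positive)) {
    positive <- if ("SIRS" %in% classes) "SIRS" else classes[1]
  }
  pred <- character(n)
  failed <- logical(n)
  for (i in seq_len(n)) {
    yi <- y[-i]
    if (length(unique(yi)) < 2 || min(table(yi)) < 2) {
      failed[i] <- TRUE
      pred[i] <- names(which.max(table(yi)))
      next
    }
    fit <- lda_fit(X[-i, , drop = FALSE], yi)
    pred[i] <- predict(fit, X[i, , drop = FALSE])
  }
  classification_metrics(pred, y, positive,
                    extra = list(subset = colnames(X),
                                 predictions = pred,
                                 failed_folds = which(failed)))
}

#' Classification metrics from predicted and true labels
#'
#' Pooled confusion counts and the derived percent metrics: sensitivity and
#' specificity with respect to the `positive` class, overall accuracy, and
#' balanced accuracy (the mean of sensitivity and specificity, the criterion
#' used under class imbalance).
#'
#' @param pred Character vector of predicted labels.
#' @param y True labels.
#' @param positive Label counted as positive.
#' @param extra Additional fields carried into the result.
#' @return An object of class `classification_result`.
#' @export
classification_metrics <- function(pred, y, positive, extra = list()) {
  pos <- y == positive
  tp <- sum(pred == positive & pos)
  tn <- sum(pred != positive & !pos)
  fn <- sum(pred != positive & pos)
  fp <- sum(pred == positive & !pos)
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  structure(c(list(accuracy = 100 * (tp + tn) / length(y),
                   sensitivity = sens, specificity = spec,
                   balanced_accuracy = (sens + spec) / 2,
                   positive = positive,
                   tp = tp, tn = tn, fp = fp, fn = fn), extra),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf(
    "<classification_result> acc %.2f%%  sens %.2f%%  spec %.2f%%  (bal %.2f%%, positive = %s)\n",
    x$accuracy, x$sensitivity, x$specificity, x$balanced_accuracy,
    x$positive))
  if (!is.null(x$subset)) cat("  features:", paste(x$subset, collapse = ", "),
                              "\n")
  invisible(x)
}

# Leave-one-out balanced accuracy of an LDA on one feature subset: the
# same mathematics as loocv_evaluate() + lda_fit(), stripped of container
# and dispatch overhead for the wrapper's inner loop (the tests assert
# equality with the reporting path). `pos` is a logical positive-class
# indicator. Returns a fraction in [0, 1].
loocv_balacc <- function(X, pos) {
  n <- nrow(X)
  p <- ncol(X)
  pred_pos <- logical(n)
  for (i in seq_len(n)) {
    pos_i <- pos[-i]
    Xi <- X[-i, , drop = FALSE]
    X0 <- Xi[!pos_i, , drop = FALSE]
    X1 <- Xi[pos_i, , drop = FALSE]
    if (nrow(X0) < 2 || nrow(X1) < 2) {   # degenerate fold: majority class
      pred_pos[i] <- nrow(X1) >= nrow(X0)
      next
    }
    m0 <- colMeans(X0)
    m1 <- colMeans(X1)
    s <- (crossprod(sweep(X0, 2, m0)) + crossprod(sweep(X1, 2, m1))) /
      (n - 3)
    w <- tryCatch(drop(chol2inv(chol(s)) %*% (m1 - m0)),
                  error = function(e) NULL)
    if (is.null(w) || !all(is.finite(w))) {
      lambda <- 1e-3 * sum(diag(s)) / p
      if (lambda <= 0) lambda <- 1e-8
      w <- drop(solve(s + diag(lambda, p), m1 - m0))
    }
    pred_pos[i] <- sum(w * X[i, ]) > sum(w * (m0 + m1)) / 2
  }
  (mean(pred_pos[pos]) + mean(!pred_pos[!pos])) / 2
}

#' Wrapper configuration
#'
#' @param subset_size Features per random subset (default 4).
#' @param n_iterations Number of random subsets to score (default 10000).
#' @param success_threshold Balanced-accuracy threshold (fraction) above
#'   which a subset counts as successful (default 0.80).
#' @param top_k Number of top-index features forming the `randset`.
#' @param seed Integer seed.
#' @return An object of class `wrapper_config`.
#' @export
wrapper_config <- function(subset_size = 4, n_iterations = 10000,
                           success_threshold = 0.80, top_k = 4, seed = 1) {
  # at or below chance every subset is "successful"; above 1 is allowed and
  # simply unattainable (useful to disable the log)
  if (success_threshold <= 0.5) stop("success_threshold must exceed 0.5")
  structure(list(subset_size = subset_size, n_iterations = n_iterations,
                 success_threshold = success_threshold, top_k = top_k,
                 seed = seed),
            class = "wrapper_config")
}

#' Random-subset wrapper feature selection
#'
#' Repeatedly draws random feature subsets (without replacement within a
#' subset), scores each by leave-one-out balanced accuracy of an LDA on the
#' subset, and logs subsets whose balanced accuracy reaches the success
#' threshold. The significance index of a feature counts its appearances in
#' successful subsets; the `randset` is the `top_k` features by index, ties
#' broken by feature-name order.
#'
#' @param feature_table Feature table (one variant) or numeric matrix.
#' @param labels Two-class labels (default `feature_table$group`).
#' @param config A [wrapper_config()].
#' @param pool Candidate feature columns (default [feature_pool()]).
#' @param positive Positive class for sensitivity (see [loocv_evaluate()]).
#' @return An object of class `wrapper_result`: `significance_index`
#'   (named, full pool), `randset`, `successful` (data frame of subsets and
#'   scores), `n_iterations`.
#' @export
wrapper_select <- function(feature_table, labels = NULL,
                           config = wrapper_config(), pool = NULL,
                           positive = NULL) {
  if (is.null(pool)) {
    pool <- if (is.data.frame(feature_table)) feature_pool(feature_table)
            else colnames(feature_table)
  }
  if (length(pool) == 0) stop("empty candidate pool")
  if (config$subset_size > length(pool)) {
    stop("subset_size exceeds the pool size")
  }
  X <- feature_matrix(feature_table, pool)
  if (is.null(labels)) labels <- feature_table$group
  y <- as.character(labels)
  classes <- unique(y)
  if (length(classes) != 2) stop("exactly two classes are required")
  if (is.null(positive)) {
    positive <- if ("SIRS" %in% classes) "SIRS" else classes[1]
  }
  pos <- y == positive
  set.seed(config$seed)
  index <- setNames(integer(length(pool)), pool)
  succ_sets <- list()
  succ_scores <- numeric(0)
  for (it in seq_len(config$n_iterations)) {
    ss <- sample(pool, config$subset_size)
    bal <- loocv_balacc(X[, ss, drop = FALSE], pos)
    if (bal >= config$success_threshold) {
      index[ss] <- index[ss] + 1L
      succ_sets[[length(succ_sets) + 1]] <- sort(ss)
      succ_scores <- c(succ_scores, 100 * bal)
    }
  }
  ord <- order(-index, names(index))
  randset <- if (any(index > 0)) {
    names(index)[ord][seq_len(min(config$top_k, sum(index > 0)))]
  } else character(0)
  successful <- if (length(succ_sets)) {
    data.frame(subset = vapply(succ_sets, paste, "", collapse = "+"),
               balanced_accuracy = succ_scores)
  } else data.frame(subset = character(0), balanced_accuracy = numeric(0))
  structure(list(significance_index = index[ord], randset = randset,
                 successful = successful,
                 n_iterations = config$n_iterations),
            class = "wrapper_result")
}

#' @export
print.wrapper_result <- function(x, ...) {
  cat(sprintf("<wrapper_result> %d iterations, %d successful subsets\n",
              x$n_iterations, nrow(x$successful)))
  top <- utils::head(x$significance_index, 6)
  cat("  top indices:",
      paste(sprintf("%s=%d", names(top), top), collapse = "  "), "\n")
  cat("  randset:", paste(x$randset, collapse = ", "), "\n")
  invisible(x)
}

#' Pairwise wrapper + LDA classification over a cohort feature table
#'
#' For every pair of groups and every preprocessing variant: run the
#' wrapper on the candidate pool, then re-evaluate the top-index features
#' at subset sizes 1..`config$top_k` (prefixes of the randset) and report
#' the size with the best leave-one-out balanced accuracy.
#'
#' @param feature_table Full feature table (all groups, both variants).
#' @param config A [wrapper_config()].
#' @param pool Candidate feature columns.
#' @param variants Variants to process.
#' @return Data frame with one row per pair x variant: `pair`, `variant`,
#'   `feature_set`, `accuracy`, `sensitivity`, `specificity`,
#'   `balanced_accuracy`.
#' @export
pairwise_classify <- function(feature_table, config = wrapper_config(),
                              pool = NULL,
                              variants = unique(feature_table$variant)) {
  groups <- unique(feature_table$group)
  if (length(groups) < 2) stop("need at least 2 groups")
  rows <- list()
  pair_id <- 0
  for (i in seq_along(groups)[-length(groups)]) {
    for (j in (i + 1):length(groups)) {
      g1 <- groups[i]; g2 <- groups[j]
      pair_id <- pair_id + 1
      for (v in variants) {
        sub <- feature_table[feature_table$variant == v &
                               feature_table$group %in% c(g1, g2), ]
        sizes <- table(sub$group)
        if (any(sizes < 2)) {
          warning(sprintf("pair %s vs %s skipped: a group has < 2 subjects",
                          g1, g2))
          next
        }
        if (any(sizes < 3)) {
          warning(sprintf("pair %s vs %s: a group has < 3 subjects", g1, g2))
        }
        cfg <- config
        cfg$seed <- config$seed + pair_id   # distinct stream per pair
        wr <- wrapper_select(sub, config = cfg, pool = pool)
        cand <- wr$randset
        if (length(cand) == 0) cand <- names(wr$significance_index)[1]
        best <- NULL
        for (k in seq_along(cand)) {
          res <- loocv_evaluate(sub, subset = cand[seq_len(k)])
          if (is.null(best) ||
              res$balanced_accuracy > best$balanced_accuracy) best <- res
        }
        rows[[length(rows) + 1]] <- data.frame(
          pair = sprintf("%s vs %s", g1, g2), variant = v,
          feature_set = paste(best$subset, collapse = ", "),
          accuracy = best$accuracy, sensitivity = best$sensitivity,
          specificity = best$specificity,
          balanced_accuracy = best$balanced_accuracy)
      }
    }
  }
  do.call(rbind, rows)
}
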