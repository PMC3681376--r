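# Dissimilarity-based clustering: euclidean distance matrix over feature
# subsets, 2-cluster k-means, cluster-quality distances and agreement with
# the SIRS-versus-infected partition.

#' Pairwise euclidean distance matrix over a feature subset
#'
#' Standard euclidean distance between subjects in the space of the chosen
#' feature columns. Features enter in their raw units by default; set
#' `standardize = TRUE` to z-score each column first.
#'
#' @param feature_table Data frame from [extract_feature_table()] (one
#'   variant), or a plain numeric matrix.
#' @param subset Character vector of feature column names.
#' @param standardize Z-score the columns first?
#' @return An n x n symmetric matrix of class `dissimilarity_matrix` with
#'   attributes `subset` and `subject_id`.
#' @export
pairwise_distance_matrix <- function(feature_table, subset = NULL,
                                     standardize = FALSE) {
  X <- feature_matrix(feature_table, subset, standardize)
  d <- as.matrix(dist(X, method = "euclidean"))
  dimnames(d) <- list(rownames(X), rownames(X))
  structure(d, subset = colnames(X), subject_id = rownames(X),
            class = c("dissimilarity_matrix", "matrix", "array"))
}

feature_matrix <- function(feature_table, subset, standardize = FALSE) {
  if (is.matrix(feature_table)) {
    X <- feature_table
    if (!is.null(subset)) X <- X[, subset, drop = FALSE]
  } else {
    if (is.null(subset)) subset <- feature_pool(feature_table)
    missing <- setdiff(subset, names(feature_table))
    if (length(missing)) {
      stop("missing feature column(s): ", paste(missing, collapse = ", "))
    }
    X <- as.matrix(feature_table[, subset, drop = FALSE])
    if (!is.null(feature_table$subject_id)) {
      rownames(X) <- feature_table$subject_id
    }
  }
  if (ncol(X) == 0) stop("empty feature subset")
  if (anyNA(X)) stop("missing values in the feature subset")
  if (standardize) X <- scale(X)
  X
}

#' Two-cluster k-means with canonical labels
#'
#' k-means with `k = 2` and multiple seeded restarts; the assignment with
#' the best (lowest) total within-cluster sum of squares wins. Labels are
#' canonicalized: cluster 1 is the larger cluster, with ties broken so that
#' the cluster containing the lowest-index subject is cluster 1. All-equal
#' rows cannot be split and yield a single cluster with a warning.
#'
#' @inheritParams pairwise_distance_matrix
#' @param seed Integer seed (assignment is deterministic given the seed).
#' @param n_restarts Number of random restarts.
#' @return Integer vector of cluster labels (1 or 2).
#' @export
kmeans_two <- function(feature_table, subset = NULL, seed = 1,
                       n_restarts = 50, standardize = FALSE) {
  X <- feature_matrix(feature_table, subset, standardize)
  if (nrow(X) < 4) stop("need at least 4 subjects")
  if (nrow(unique(X)) < 2) {
    warning("all points identical; returning a single cluster")
    return(rep(1L, nrow(X)))
  }
  set.seed(seed)
  km <- kmeans(X, centers = 2, nstart = n_restarts)
  cl <- km$cluster
  n1 <- sum(cl == 1)
  n2 <- sum(cl == 2)
  swap <- n2 > n1 || (n1 == n2 && cl[1] == 2)
  if (swap) cl <- 3L - cl
  cl
}

#' Intraclass / interclass distances and clustering cost
#'
#' Quality of a 2-cluster assignment, computed from the dissimilarity
#' matrix: `c_k` is the mean pairwise distance within cluster `k`
#' (singletons give 0 with a warning), `d_kj` the mean euclidean distance
#' from the members of cluster `k` to the centroid of cluster `j`
#' (recovered from the distance matrix by the standard centroid identity),
#' and `cost = (c1 + c2) / (d12 + d21)` -- compact, well-separated clusters
#' score low.
#'
#' @param assignment Integer vector of cluster labels (1/2).
#' @param dmatrix A `dissimilarity_matrix` from
#'   [pairwise_distance_matrix()].
#' @return List with `n1`, `n2`, `c1`, `c2`, `d12`, `d21`, `cost` and a
#'   `definition` string recording the formulas.
#' @export
cluster_quality <- function(assignment, dmatrix) {
  stopifnot(length(assignment) == nrow(dmatrix))
  if (!all(assignment %in% c(1L, 2L)) || length(unique(assignment)) < 2) {
    stop("need two non-empty clusters labelled 1 and 2")
  }
  d2 <- unclass(dmatrix)^2
  within <- function(k) {
    idx <- which(assignment == k)
    if (length(idx) == 1) {
      warning(sprintf("cluster %d is a singleton; intraclass distance 0", k))
      return(0)
    }
    sub <- dmatrix[idx, idx]
    mean(sub[upper.tri(sub)])
  }
  # mean distance from members of k to the centroid of j; for euclidean
  # distances  d(p, centroid(C))^2 = mean_q d(p,q)^2 - mean_{q<q'} pairwise^2 / 2
  to_centroid <- function(k, j) {
    ik <- which(assignment == k)
    ij <- which(assignment == j)
    spread <- mean(d2[ij, ij]) / 2          # includes zero diagonal
    mean(sqrt(pmax(0, rowMeans(d2[ik, ij, drop = FALSE]) - spread)))
  }
  c1 <- within(1L); c2 <- within(2L)
  d12 <- to_centroid(1L, 2L); d21 <- to_centroid(2L, 1L)
  list(n1 = sum(assignment == 1L), n2 = sum(assignment == 2L),
       c1 = c1, c2 = c2, d12 = d12, d21 = d21,
       cost = (c1 + c2) / (d12 + d21),
       definition = paste(
         "c_k = mean within-cluster pairwise distance;",
         "d_kj = mean member-to-other-centroid distance;",
         "cost = (c1+c2)/(d12+d21)"))
}

#' Agreement of a 2-cluster assignment with the infection status
#'
#' Subjects are binarized as positive = infected (sepsis or septic shock)
#' and negative = SIRS. Each cluster is mapped to the class holding its
#' majority (ties go to the positive class); sensitivity, specificity and
#' accuracy of the induced classification are returned as percentages.
#'
#' @param assignment Integer cluster labels.
#' @param labels Group labels, or a logical vector of positives.
#' @param positive Group labels counted as positive.
#' @return List with `sensitivity`, `specificity`, `accuracy` (percent) and
#'   the confusion counts.
#' @export
cluster_class_agreement <- function(assignment, labels,
                                    positive = c("sepsis", "septic_shock")) {
  if (is.logical(labels)) pos <- labels
  else pos <- as.character(labels) %in% positive
  if (all(pos) || !any(pos)) stop("one of the two classes is absent")
  stopifnot(length(assignment) == length(pos))
  pred <- logical(length(pos))
  for (k in unique(assignment)) {
    idx <- assignment == k
    n_pos <- sum(pos[idx])
    pred[idx] <- n_pos >= sum(idx) / 2   # tie -> positive
  }
  tp <- sum(pred & pos); tn <- sum(!pred & !pos)
  fp <- sum(pred & !pos); fn <- sum(!pred & pos)
  list(sensitivity = 100 * tp / (tp + fn),
       specificity = 100 * tn / (tn + fp),
       accuracy = 100 * (tp + tn) / length(pos),
       tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Predefined clustering feature subsets
#'
#' Named feature groupings mirroring the clustering experiments of the
#' study design: ultradian DWT entropies, neurogenic/metabolic entropies,
#' CWT entropy combinations, sample-entropy summaries, raw temperature
#' summaries and CWT energies.
#'
#' @return Named list of character vectors of feature-column names.
#' @export
cluster_feature_subsets <- function() {
  list(
    dwt_high_ultradian_entropy = c("WEn_s5", "WEn_s6"),
    cwt_entropy_neuro_meta = c("CWTentro1", "CWTentro2"),
    cwt_entropies = paste0("CWTentro", 1:4),
    cwt_entropy_ultradian = c("CWTentro3", "CWTentro4"),
    sampen_sumen = c("SampEn", "sumEn"),
    cwt_entropy_all_neuro = c("CWTentro", "CWTentro1"),
    dwt_low_ultradian_entropy = c("WEn_s7", "WEn_s8"),
    dwt_neuro_metabolic_entropy = c("WEn_s1", "WEn_s2", "WEn_s3"),
    t_mean_sd = c("T_mean", "T_sd"),
    cwt_energy = paste0("CWTen", 1:4))
}

#' Evaluate 2-cluster partitions over several feature subsets
#'
#' Runs [kmeans_two()], [cluster_quality()] and
#' [cluster_class_agreement()] for each subset and collects the results in
#' one table.
#'
#' @param feature_table Feature table restricted to one variant.
#' @param subsets Named list of feature subsets (default
#'   [cluster_feature_subsets()]).
#' @param seed Seed passed to [kmeans_two()].
#' @param positive Positive-class group labels.
#' @return Data frame with one row per subset: cluster sizes, intraclass
#'   and interclass distances, cost, sensitivity, specificity, accuracy.
#' @export
evaluate_clusterings <- function(feature_table,
                                 subsets = cluster_feature_subsets(),
                                 seed = 1,
                                 positive = c("sepsis", "septic_shock")) {
  rows <- lapply(names(subsets), function(nm) {
    ss <- subsets[[nm]]
    cl <- kmeans_two(feature_table, ss, seed = seed)
    dm <- pairwise_distance_matrix(feature_table, ss)
    q <- cluster_quality(cl, dm)
    a <- cluster_class_agreement(cl, feature_table$group, positive)
    data.frame(subset = nm, n1 = q$n1, n2 = q$n2, c1 = q$c1, c2 = q$c2,
               d12 = q$d12, d21 = q$d21, cost = q$cost,
               sensitivity = a$sensitivity, specificity = a$specificity,
               accuracy = a$accuracy)
  })
  out <- do.call(rbind, rows)
  out[order(out$cost), ]
}
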