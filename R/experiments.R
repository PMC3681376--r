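# Canned cohort-level experiments: parameter recovery of the wrapper
# selection, SIRS-versus-shock classification on the default profiles, and
# calibration of the rank-sum test. These are the package's headline
# simulation studies; the analysis scripts and the acceptance checks both
# run them.

#' Ultradian-band entropy feature names
#'
#' The features that measure complexity in the ultradian range: DWT wavelet
#' entropies at scales 4-9 and the CWT entropies of the two low-frequency
#' bands.
#'
#' @param n_scales Number of DWT scales in the feature table.
#' @return Character vector of feature names.
#' @export
ultradian_entropy_features <- function(n_scales = 9) {
  c(paste0("WEn_s", 4:n_scales), "CWTentro3", "CWTentro4")
}

#' One wrapper parameter-recovery run
#'
#' Generates a two-group cohort from [recovery_profiles()] -- identical in
#' every respect except the regularity of one ultradian sub-band -- extracts
#' the `sign_mdetr` feature table, and runs the random-subset wrapper. If
#' the wrapper works, the top-ranked features must be ultradian-band
#' entropies, because nothing else differs between the groups.
#'
#' @param seed Cohort and wrapper seed.
#' @param n_per_group Subjects per group.
#' @param n_iterations Wrapper iterations.
#' @return List with `top_feature`, `randset`, `significance_index` and
#'   `top_is_ultradian`.
#' @export
wrapper_recovery_run <- function(seed, n_per_group = 20,
                                 n_iterations = 600) {
  co <- generate_cohort(recovery_profiles(),
                        cohort_config(n_per_group = n_per_group,
                                      seed = seed))
  ft <- extract_feature_table(co, variants = "sign_mdetr")
  wr <- wrapper_select(ft, config = wrapper_config(
    n_iterations = n_iterations, seed = seed))
  top <- names(wr$significance_index)[1]
  list(top_feature = top, randset = wr$randset,
       significance_index = wr$significance_index,
       top_is_ultradian = top %in% ultradian_entropy_features())
}

#' One SIRS-versus-septic-shock classification run
#'
#' Generates SIRS and septic-shock subjects from the default study
#' profiles, runs wrapper feature selection and evaluates the selected set
#' by leave-one-out LDA.
#'
#' @inheritParams wrapper_recovery_run
#' @return One-row data frame (see [pairwise_classify()]).
#' @export
sirs_shock_classification_run <- function(seed, n_per_group = 20,
                                          n_iterations = 600) {
  profs <- default_group_profiles()[c("SIRS", "septic_shock")]
  co <- generate_cohort(profs, cohort_config(n_per_group = n_per_group,
                                             seed = seed))
  ft <- extract_feature_table(co, variants = "sign_mdetr")
  pairwise_classify(ft, config = wrapper_config(
    n_iterations = n_iterations, seed = seed))
}

#' Empirical type-I error of the rank-sum test under the global null
#'
#' Draws both groups from the same normal distribution `n_sims` times and
#' reports the fraction of two-sided p-values below `alpha`.
#'
#' @param n_sims Number of simulations.
#' @param n_per_group Observations per group.
#' @param alpha Nominal level.
#' @param seed Seed.
#' @return Rejection rate (a fraction).
#' @export
ranksum_type1_error <- function(n_sims = 2000, n_per_group = 15,
                                alpha = 0.05, seed = 1) {
  set.seed(seed)
  labels <- rep(c("a", "b"), each = n_per_group)
  rejections <- vapply(seq_len(n_sims), function(i) {
    p <- ranksum_pairwise(rnorm(2 * n_per_group), labels)
    unname(p["p_1_2"]) < alpha
  }, TRUE)
  mean(rejections)
}
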