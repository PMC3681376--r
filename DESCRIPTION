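Package: thermentropy
Title: Wavelet and Multiscale Entropy Analysis of Continuous Body Temperature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Complexity analysis of continuously monitored body temperature in
    systemic inflammation. Decomposes 0.1-Hz temperature recordings with a
    discrete Meyer wavelet transform into nine dyadic scales spanning the
    neurogenic, metabolic and ultradian frequency bands, and computes wavelet
    energy and Shannon wavelet entropy per scale, continuous-wavelet band
    features, and multiscale sample entropy. Provides the accompanying
    statistical battery (Lilliefors, rank-sum, Kruskal-Wallis with Dunn and
    Bonferroni follow-up, Spearman correlation against severity scores),
    dissimilarity-based two-cluster evaluation, and wrapper feature selection
    with linear discriminant analysis under leave-one-out cross-validation.
    Includes a synthetic-cohort generator that emulates band-structured,
    quantized 24-hour temperature signals with group-dependent complexity, so
    the full pipeline is testable without patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    nortest,
    withr
Config/testthat/edition: 3
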