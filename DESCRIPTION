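Package: pottsfocus
Title: Quantity-Relevance Trade-Off for Protein Fitness Prediction from
    Sequence Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the fitness effects of single point mutations from a
    multiple sequence alignment with sparse (K-link) Potts models, and selects
    the optimal sub-alignment around a wild-type sequence by balancing the
    quantity of sequences against their relevance (Hamming proximity to the
    wild type). Implements analytic estimators of the statistical variance of
    the predictor, a linear bias model driven by the mean Hamming distance
    with a fitted bias factor, focusing-cutoff predictors (bias-variance and
    signal-to-noise heuristics), exponentially biased alignment subsampling,
    and a self-contained lattice-protein ground-truth bench (compact 27-mer
    folds on the 3x3x3 cube) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
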