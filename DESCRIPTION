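Package: megrsa
Title: Time-Resolved MEG Decoding and Representational Similarity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for time-resolved multivariate decoding of
    sensor-level MEG epochs and representational similarity analysis (RSA).
    Covers trial rejection, baseline normalization and temporal smoothing;
    pairwise support-vector decoding into time-resolved representational
    dissimilarity matrices (RDMs); representational clustering and
    cross-classification across experimental factors and image identity;
    model RDMs from GIST and HMAX image features, explicit factor models and
    externally computed network activations, compared to brain RDMs by
    (partial) Spearman correlation; and nonparametric inference by
    sign-permutation cluster-size tests and bootstrap latency confidence
    intervals. A synthetic-data generator produces factorial designs,
    stimulus images with controlled RMS statistics, and multi-subject epochs
    with known injected effects so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    yaml,
    png,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
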