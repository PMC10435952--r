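Package: paireval
Title: Paired Evaluation of Predictive Models with Rankable Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the performance of machine-learning models in
    small-sample biological and clinical studies by decomposing evaluation
    into rankable pairs of test samples. The area under the ROC curve (AUC)
    is estimated as the fraction of rankable pairs a model orders correctly,
    computed either by exhaustive pair scoring or by an O(n log n)
    inversion-counting merge sort. Supports leave-pair-out cross-validation
    with pluggable model adapters, exact contingency-table comparison of two
    models (Fisher and McNemar tests), detection of outlier samples via
    sample-specific AUC, quantification of known confounders by contrasting
    confounder-matched and mismatched pairs, and a synthetic-data generator
    emulating confounded expression-like datasets with technical replicates
    and injected outliers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    knitr,
    optparse,
    ranger,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
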