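Package: adeforest
Title: Ensembles of Randomized Trees over Semantic Spaces of Clinical Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects adverse drug events in care-episode data by learning an
    ensemble of semantic spaces -- one skip-gram embedding per clinical data
    type (note words, diagnosis codes, drug codes, measurement types) and
    context window size -- and building forests of randomized trees under
    three semantic-space utilization strategies: fused diverse representations
    (FDR), randomized diverse representations with feature subsampling
    (RDR-FS), and randomized diverse representations without feature
    subsampling (RDR-ALL). Includes count-weighted bag-of-embeddings
    featurization, a count-based baseline, cross-validated evaluation with
    accuracy, AUC, average tree accuracy and ensemble diversity, Friedman and
    Bergmann-Hommel significance testing, a semantic-space pool-size
    experiment, and a synthetic electronic-health-record generator so the
    whole pipeline runs without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    rpart,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    withr,
    jsonlite,
    Matrix,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
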