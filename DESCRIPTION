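Package: credassign
Title: Temporal Credit Assignment with Eligibility-Trace and Tabular Learning Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and model-based analysis of two-alternative reward
    learning with sequentially delayed feedback. Provides a generator for the
    delayed-reward task (eight stimuli on integer-rounded Gaussian reward
    random walks, two-trial delayed feedback, conjoint or disjoint feedback
    rendering), retrospective (replacing eligibility trace) and prospective
    (delay-indexed tabular) reinforcement-learning models with a hybrid
    softmax decision rule over locally z-normalized values, penalized
    maximum-likelihood fitting by differential evolution, parameter- and
    model-recovery studies, and behavioral signature analyses (stay/switch
    regressions, pair-type predictive accuracy, credit-assignment gradients,
    and condition contrasts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    stats,
    generics,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
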