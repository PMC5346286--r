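Package: odacta
Title: Optimal Discriminant and Classification Tree Analysis for
    Pharmacoepidemiologic Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling adverse drug events in electronic
    medical record (EMR) cohorts with exact non-parametric methods.
    Implements trigger-tool case definitions for new, and persistent,
    drug-associated sexual dysfunction after 5-alpha-reductase-inhibitor
    exposure; days-of-supply interval-union exposure duration; 2x2
    effect metrics (number needed to harm, risk ratio, effect strength
    for sensitivity); univariable optimal discriminant analysis (ODA)
    with permutation p-values and Sidak multiple-comparison control;
    hierarchically optimal classification tree analysis (CTA) with a
    minimum-endpoint-size constraint and temporal holdout validation;
    and a synthetic EMR cohort generator with a planted threshold-tree
    outcome model for end-to-end testing and method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
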