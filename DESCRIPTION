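Package: mzclass
Title: Interpretable Classification of Untargeted Metabolomics Feature Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Benchmarks six classifier families (multilayer perceptron, gradient
    boosting, random forest, penalised logistic regression, support vector
    machine, linear discriminant analysis) on whole subject-by-feature
    metabolomics tables under a repeated 60/40 Monte-Carlo train/test protocol,
    selects hyperparameters by mean Matthews correlation coefficient, ranks
    chemical features by absolute-averaged Shapley attributions, and annotates
    top-ranked m/z features by adduct-aware monoisotopic-mass matching against a
    local compound table within a ppm tolerance. Includes a synthetic-data
    generator with planted biomarkers so the whole pipeline is testable without
    any cohort download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    MASS,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
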