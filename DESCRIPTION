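Package: baglasso
Title: Knowledge-Guided Post-Processing of Lasso Variable Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage workflow that makes expert elicitation of biological
    relevance feasible for high-dimensional regression. Stage one fits a
    cross-validated (adaptive) lasso on a first data portion and builds, for
    every selected covariate, a "bag" of potential substitutes by correlation
    ranking, correlation thresholding, or replacement ordinary-least-squares
    mean squared error. A domain expert labels only the union of the bags;
    selected covariates are then switched for biologically relevant bag
    members by fixed rules, and the final sparse model is refit on a second
    portion. Includes a block-correlated Gaussian simulation engine, the
    full replicated simulation study with prediction-error ratios, bootstrap
    confidence intervals, favorable-substitution rates and estimation-error
    summaries, plus worksheet input/output for real elicitation rounds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
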