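Package: idionet
Title: Person-Specific Symptom Networks from Ecological Momentary
    Assessment Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Idiographic (person-specific) analysis of intensive longitudinal
    symptom data such as post-concussion symptom ratings collected by
    ecological momentary assessment. Accounts for nonstationarity -- recovery
    trends and diurnal/ultradian cycles -- either by embedding temporal
    variables as nodes in a regularized partial-correlation network, or by
    LASSO-selected polynomial/sinusoidal detrending followed by network
    estimation on the residuals. Networks are Gaussian graphical models
    estimated by a graphical lasso with extended-BIC model selection; node
    centrality (strength, expected influence) and raw-versus-detrended
    comparisons are provided, together with a synthetic-data generator with
    known ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
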