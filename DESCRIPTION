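Package: neoscore
Title: Multi-Gene Expression Scores as Predictors of Neoadjuvant
    Chemotherapy Response in Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Approximates two commercial breast-cancer prognostic
    signatures, the 12-gene molecular score and the 21-gene recurrence
    score, from probe-level microarray expression matrices, and compares
    them head-to-head as predictors of pathologic complete response to
    neoadjuvant chemotherapy in estrogen-receptor-positive,
    HER2-negative disease. Provides probe-to-gene collapsing, simple
    scaling normalization, percentile floor thresholding of the
    proliferation gene group, per-cohort z-standardization,
    cohort-adjusted logistic regression with odds ratios per standard
    deviation, marginally standardized response-probability curves, a
    proliferation-threshold sensitivity sweep, and a multi-cohort
    latent-factor simulator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
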