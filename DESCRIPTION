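Package: abxpls
Title: Determinants of Antibiotic Consumption via Partial Least Squares
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models national antibiotic consumption (standard units per 1000
    population) as a function of collinear, trending socioeconomic and
    infrastructure determinants observed over few years. Implements
    univariate-response partial least squares regression (NIPALS) from
    scratch, variable importance in projection (VIP) scores, loading-based
    determinant screening, leave-one-out cross-validated model comparison
    with bias-corrected RMSEP, bootstrap prediction intervals, and
    disaggregation of national predictions to sub-national units. Ships a
    synthetic determinant-panel generator with known ground truth so the
    whole pipeline is testable without access to the original data sources,
    plus the published India 2000-2010 consumption series and the fitted
    health-and-transport-infrastructure prediction equation as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
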