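Package: demrisk
Title: Dementia Risk Index Calculation, Comparison and Sensitivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes five published point-based dementia risk indices
    (ANU-ADRI, CAIDE, CogDrisk, LIBRA and LIBRA2) from harmonized cohort
    variables using declarative weight tables, and compares their predictive
    performance for incident dementia. Provides a synthetic cohort generator
    (Gaussian-copula categorical structure, logistic outcome model, MAR
    missingness) so the full analysis is testable without access to
    restricted cohort data; harmonization of raw survey, clinical and
    registry measurements into index-ready factor levels; z-standardized
    logistic models with McFadden pseudo R-squared; rank-based AUCs with
    DeLong covariance, a gated global-then-pairwise comparison procedure and
    contrasts against a demographics-only reference model; stratified
    analyses; and sensitivity analyses via joint multivariate-normal
    multiple imputation with Rubin's-rules pooling (RVI and FMI diagnostics)
    and index-specific available-case refits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    MASS,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
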