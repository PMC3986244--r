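Package: lipidcvd
Title: Lipidomic Case-Control Association and Cardiovascular Risk Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for plasma lipidomic case-control studies of cardiovascular
    risk in treated HIV infection: logistic association scans reporting odds
    ratios per interquartile range with Benjamini-Hochberg false-discovery-rate
    control, cohort characteristics tables (Mann-Whitney U and Fisher's exact
    comparisons), a repeated class-stratified k-fold cross-validation framework
    with in-fold univariate ROC-AUC feature selection and a soft-margin linear
    support vector classifier (feature-inclusion stability reporting), a
    declarative evaluator for 10-year coronary heart disease risk equations
    (Cox-survival and log-rate forms), and a synthetic cohort generator with
    known injected effect sizes for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
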