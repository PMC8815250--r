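Package: chemosig
Title: Chemoresponse Gene-Signature Discovery for BRCA Wild-Type Ovarian Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end workflow for discovering and validating transcriptomic
    signatures of response to first-line platinum chemotherapy in BRCA
    wild-type high-grade serous ovarian cancer. Implements count-based
    differential expression (median-of-ratios normalization, empirical-Bayes
    batch adjustment, negative-binomial Wald tests with trend-shrunk
    method-of-moments dispersions), RT-qPCR validation statistics (geNorm
    reference stability, delta-Ct and delta-delta-Ct quantities, exact
    Wilcoxon rank-sum tests with Hodges-Lehmann shift estimates,
    cross-platform concordance regression), a Brier-score-filtered
    cross-validated random-forest signature ranking, four-parameter-logistic
    dose-response fitting with plasma-concentration resistance calls and
    label-randomization tests for cell-line panels, Fisher-exact
    over-representation analysis, and a seeded synthetic-data generator that
    reproduces the statistical structure of the study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    MASS,
    randomForest,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
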