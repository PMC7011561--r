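Package: tehsplit
Title: Treatment Effect Heterogeneity Tests for Randomised Trials via
    Repeated Data Splitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Omnibus hypothesis tests for treatment effect heterogeneity in
    two-arm randomised controlled trials with binary outcomes, with strict
    control of the type I error. The trial is repeatedly and randomly split
    into two arm-balanced halves; a statistical or machine-learning model
    trained on each half predicts individual treatment effects for the
    held-out half, so that every prediction is out-of-sample. A one-sided
    two-sample test inside the held-out subgroup predicted to benefit from
    switching off the standard of care tests for crossover heterogeneity
    (a benefitting subgroup), and a stacked logistic likelihood-ratio test
    of cross-fitted predictions tests the added predictive benefit of the
    machine-learning model over a baseline generalised linear model. The
    per-split p values are merged into a single valid aggregate p value by
    quantile scaling with a log-correction for the adaptive search over
    quantile levels. A synthetic-trial generator with configurable
    heterogeneity supports calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    ggplot2,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
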