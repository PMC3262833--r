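Package: strokeclass
Title: Severity Classification Instruments and Outcome Prediction for Acute Ischemic Stroke Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements dichotomized severity-classification instruments for
    acute ischemic stroke -- the Alberta Stroke Program Early CT Score
    (ASPECTS), the Boston Acute Stroke Imaging Scale (BASIS), the admission
    NIHSS cut at 10, and their combination into concordant/discordant strata
    -- together with the statistical machinery used to evaluate them against
    6-month modified Rankin outcomes: 2x2 diagnostic metrics with Wilson
    intervals, McNemar's paired test, odds ratios with Woolf intervals,
    r x c chi-square, Wilcoxon rank-sum, Welch t, and iteratively reweighted
    least-squares logistic regression with forced-entry and stepwise modes.
    A fixture layer reconstructs published contingency tables from printed
    counts, and a seeded synthetic-cohort generator calibrated to published
    marginal and conditional rates lets the whole pipeline run end-to-end
    with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
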