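Package: vasokinetics
Title: Circulating Progenitor-Cell Kinetics and Vasoplegia Classification
    After Cardiopulmonary Bypass
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the kinetics of circulating progenitor
    cells (CD34+, CD133+, VEGFR2+, hematopoietic stem cells and
    endothelial progenitor cells, enumerated by flow cytometry as counts
    per million lympho-monocytic events) across intra-operative time
    points in cardiopulmonary-bypass patients, and for relating those
    kinetics to post-operative vasoplegia. Provides a synthetic cohort
    generator with configurable trajectory distributions, log fold-change
    feature construction against multiple baselines, norepinephrine-dose
    group assignment, exact small-sample rank tests (Mann-Whitney,
    Wilcoxon signed rank) with enumerated null distributions, a
    Lilliefors-corrected Kolmogorov-Smirnov normality check, Cohen's d
    effect sizes with simulation-based and analytic power, leave-one-out
    evaluation of self-contained logistic-regression and
    gradient-boosted-stump classifiers, permutation significance testing
    of classifier error under label-shuffle and uniform-feature nulls,
    optimal one-dimensional risk-score pair matching by dynamic
    programming, and a reproducible end-to-end pipeline driver.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    nortest,
    optparse,
    testthat (>= 3.0.0),
    xgboost
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
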