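Package: drivescreen
Title: Simulation and Evaluation of a Cognitive Screening Battery for
    Fitness-to-Drive Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Headless simulation and statistical evaluation of a five-subtest
    web-based cognitive screening battery used to predict simulated driving
    performance. Provides a synthetic cohort generator with latent-ability
    linked error counts, a discrete-time engine for the five subtests driven
    by pluggable respondent agents, rank-based score normalization into [0,1],
    the mean-plus-one-SD driving-performance grouping rule, and a screening
    evaluation suite: Pearson correlations with t-based p-values, one-sided
    Mann-Whitney U tests, empirical and binormal ROC curves, AUC with the
    Hanley-McNeil standard error, and cutoff tables reporting sensitivity,
    specificity and efficiency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
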