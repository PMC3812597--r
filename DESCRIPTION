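Package: copbalance
Title: Balance Complexity Analysis of Center-of-Pressure Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies human standing balance from force-platform
    recordings. Converts four load-cell force channels to a
    center-of-pressure (COP) trajectory, decomposes the medial-lateral and
    anterior-posterior sway channels with (noise-assisted multivariate)
    empirical mode decomposition, reconstructs the sub-2 Hz sway band from
    selected intrinsic mode functions, and summarises balance as a
    complexity index, the area under the multiscale (or multivariate
    multiscale) sample-entropy curve. Also provides the device-validation
    statistics used to characterise low-cost force platforms (static error
    ratios, a dynamic radius statistic, lagged cross-correlation, and the
    intraclass correlation coefficient), seeded synthetic sway cohorts with
    four graded test conditions, and a cohort comparison layer reporting
    per-condition improvement rates with paired significance tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
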