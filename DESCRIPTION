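Package: ocsntools
Title: Engagement Analysis for Online Cessation Support Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing posting behaviour in online cessation
    support networks (OCSNs) from interaction metadata (posts and comments
    with timestamps and thread linkage). Provides a cleaning pipeline
    (within-thread exact-text deduplication by content hash, staff-account
    exclusion), rolling-window engagement classification into highly and
    minimally engaged users, contribution shares with bootstrap confidence
    intervals, temporal pattern estimation (monthly first-time post series
    with exact Poisson intervals; day-of-week activity means with
    weekly-cluster robust standard errors and holiday-week exclusion),
    early prediction of minimal engagement from first-day and first-week
    activity via logistic models with holdout evaluation, reporting
    utilities, and a seeded synthetic activity-stream generator with
    artifact injection for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    jsonlite,
    yaml,
    digest,
    sandwich,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
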