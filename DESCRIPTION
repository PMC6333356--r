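Package: dwellsense
Title: In-Home Sensor Analytics for Remote Dementia Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analytics for passive in-home monitoring of people living with
    dementia. Builds hourly sensor firing patterns from ambient sensor event
    logs, learns routine activity profiles per time of day with non-negative
    matrix factorisation solved by alternating constrained least squares,
    categorises behaviour clusters by median-absolute-deviation of their
    sizes, and fuses rare-pattern alerts with body-temperature alerts into
    early urinary-tract-infection warnings. Also provides an
    isolation-forest daily-routine anomaly detector, a rule-based night-time
    sleep analyser driven by bed-pressure epochs with adaptive personal
    deviation boundaries, a NEWS2-style daily health score with an adaptive
    personal confidence interval, evaluation statistics, and a deterministic
    synthetic smart-home cohort simulator for development and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    jsonlite,
    yaml,
    e1071,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
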