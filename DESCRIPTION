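Package: abpmscreen
Title: Validation of Unattended Office Blood Pressure Screening Against
    Ambulatory Monitoring
Version: 0.1.0
Authors@R:
    person("abpmscreen", "authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating unattended automated office blood
    pressure (uAOBP) as a screening test for hypertension with 24-hour
    ambulatory blood pressure monitoring (ABPM) as the reference
    standard.  Ingests timestamped ambulatory cuff readings, applies
    IDACO completeness criteria (at least 10 daytime and 5 nighttime
    readings), computes daytime, nighttime and time-weighted 24-hour
    averages, classifies subjects into sustained, white-coat, masked
    and normotensive phenotypes at configurable screen cutoffs, and
    reports diagnostic validity (sensitivity, specificity, predictive
    values, likelihood ratios, AUROC), paired tests, and Bland-Altman
    agreement with the Pitman-Morgan test.  A circadian blood-pressure
    cohort simulator with known latent phenotypes supports end-to-end
    validation of the pipeline.
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
    optparse
Config/testthat/edition: 3
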