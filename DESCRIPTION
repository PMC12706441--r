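Package: surveyfraud
Title: Fraud Detection, Calibration, and Removal for Web-Based Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Screens incentivized web-based survey responses for fraud.
    Implements a signed fraud-point criteria engine (protective and
    suspicious evidence such as plausible free text, honeypot hits,
    nonsensical answer combinations, suspicious email patterns,
    sub-threshold completion times, duplicate and batch submissions),
    control-based sensitivity/specificity calibration with score cut-point
    selection into include/exclude/review buckets, rule-based review
    resolution, categorical risk profiling, stage-by-stage dataset
    accounting, and a seeded synthetic respondent-cohort generator
    emulating genuine respondents, eligible duplicators, misrepresenting
    humans, and bots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
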