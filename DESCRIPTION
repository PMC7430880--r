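Package: simvalid
Title: Validity Evidence and Contrasting-Groups Standard Setting for
    Simulator-Based Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing validity evidence of simulator-based surgical
    skills assessment: aggregation of Likert questionnaire domains (content
    validity), construct-validity screening of performance metrics with
    variance-gated two-sample t-tests from raw records or printed summary
    statistics, direction-aware min-max composite scoring on a 0-100 scale,
    and contrasting-groups standard setting via the intersection of fitted
    group Gaussians, with theoretical and empirical false-positive and
    false-negative rates. Includes a seeded truncated-normal cohort generator
    so the full pipeline can be reproduced from published group summary
    statistics alone.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    car
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
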