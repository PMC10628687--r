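Package: cvh8
Title: Pediatric Life's Essential 8 Scoring, Joinpoint Trends and
    Cross-Lagged Panel Models for Multiwave Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying cardiovascular health (CVH) in school-aged
    children from multiwave cross-sectional surveys. Computes the eight
    pediatric Life's Essential 8 component scores (diet, physical activity,
    nicotine exposure, sleep, body-mass index, blood lipids, blood glucose,
    blood pressure; each 0-100) from individual records using configurable
    scoring rubrics, LMS growth references and age-sex-height blood-pressure
    references; estimates age- and sex-adjusted temporal trends by joinpoint
    (segmented linear) regression with permutation-based model selection;
    fits cross-lagged panel models between behaviour and factor scores
    across wave blocks with maximum-likelihood fit indices; and ships a
    synthetic multiwave cohort generator with known ground truth for
    end-to-end validation. Includes Fisher-Jenks natural-breaks
    classification and a reproducible pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
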