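Package: somnoscreen
Title: Screening for Severe Sleep Disorders in Young Children from 14-Day Sleep Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to screen children aged 0-83 months for severe sleep
    disorders from 14-day parental sleep logs. Sleep diaries are rasterized
    to a 5-minute sleep/wake epoch grid, ten summary variables are extracted
    (including sigmoid-fitted wake-up and bed times with jitter-averaged
    nonlinear least squares), and each child is classified with published
    per-age-group Fisher discriminant functions. The training pipeline
    (two-group linear discriminant analysis with stepwise Wilks' lambda
    variable selection, Bartlett's chi-square, and leave-one-out
    cross-validation) is included so new classifier banks can be fitted and
    validated, together with a seeded synthetic cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
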