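Package: actema
Title: Day-Level Agreement Between Self-Reported and Accelerometer-Measured Exercise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Validates single-item end-of-day exercise self-reports
    (ecological momentary assessment, EMA) against minute-level
    accelerometer data over long observation periods.  Implements social-day
    assembly (3 a.m. to 2:59 a.m.), step-based non-wear detection, wear-time
    validity screening, sliding-window classification of exercise days from
    moderate-to-vigorous physical activity (MVPA) minutes, per-participant
    and pooled Cohen's kappa with an asymptotic standard error, sensitivity
    sweeps over the bout-duration and intensity criteria, linear-regression
    screens of person-level correlates of agreement, and a synthetic-cohort
    generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
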