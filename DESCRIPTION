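Package: glyco
Title: Glycemic Variability and Excursion Analysis for Continuous Glucose
    Monitoring in Growing Pigs
Version: 0.1.0
Authors@R:
    person("glyco", "authors", email = "cgm@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse continuous glucose monitoring (CGM) traces
    from free-moving growing pigs: signal repair (linear and
    shape-preserving Hermite interpolation of missing points),
    Savitzky-Golay smoothing, classical glycemic-variability metrics
    (MAGE, CONGA, time-in-range), baseline-band peak/nadir excursion
    detection with per-period summaries over night, day and postprandial
    windows, CGM-versus-blood time-shift estimation by frequency-domain
    cross-correlation, hematocrit-based plasma-to-blood conversion,
    Bland-Altman agreement, a repeated-measures and nonparametric
    statistical layer, and a seeded synthetic-cohort generator so that
    every stage of the pipeline is testable without sensor downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
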