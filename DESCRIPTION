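Package: circbp
Title: Piecewise-Exponential Modelling of Circadian Blood-Pressure Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a piecewise-exponential model of the circadian blood-pressure
    rhythm to multi-day cuffless-monitor recordings. Each subject-day is
    described by five parameters (nocturnal baseline, daytime increment,
    exponential rate, wake time and bedtime) estimated by bounded nonlinear
    least squares, separately for systolic and diastolic pressure, in a basic
    variant and an extended variant that carries the previous day's baseline
    and increment into the pre-wake night segment. Includes weighted-residual
    diagnostics, per-subject and population summaries of intra- and
    inter-individual variability (medians, ranges, coefficients of variation),
    a synthetic cuffless-monitor data generator with known ground truth,
    CSV import/export and multi-day profile and residual plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
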