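Package: allovf
Title: Allometric Modelling of Ventricular Fibrillation Probability from
    ST-Segment Deviation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits and evaluates an allometric (power-law) model relating the
    probability of ventricular fibrillation to the electrocardiographic
    ST-segment deviation. Provides prediction and inversion of fitted
    log-log curves, the curve-resampling (piecewise quadratic, 0.025 mm
    grid) and log-log ordinary least squares fitting pipeline used to
    estimate the allometric exponent and intercept from sparse clinical
    event-rate tables, two curve-aggregation procedures (probability-space
    averaging with refit and half-SD band; log-space mean with SEM band),
    and a seeded binomial cohort simulator for parameter-recovery studies.
    All user-facing functions take data frames and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
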