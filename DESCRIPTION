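Package: neurocpd
Title: Cross-Task Single-Neuron Selectivity via Time-Resolved Coefficients
    of Partial Determination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing trial-structured single-neuron spike
    recordings from cued reaching tasks. Provides event-aligned
    sliding-window firing-rate estimation, multifactorial nested-ANOVA
    encoding models with aliasing-aware contrast coding, time-resolved
    coefficients of partial determination (CPD) with significance
    masking, response-period selectivity classification across task
    variants, population summary fractions, and a Poisson/gamma-renewal
    spike-train simulator with planted, task-dependent selectivity that
    supplies ground truth for parameter-recovery validation.
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
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
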