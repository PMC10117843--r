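Package: occbias
Title: Occupational Cohort Mortality Analysis with Quantitative Bias Adjustment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for reanalysis of occupational cohort mortality studies:
    person-year tabulation with lagged time-dependent exposure, standardized
    mortality ratios (SMR) with exact Poisson confidence intervals against
    reference rate tables, explicit nested case-control risk sets matched on
    attained age, conditional-likelihood rate-ratio models, negative control
    outcome adjustment for unmeasured confounding, and indirect SMR adjustment
    via the confounding risk ratio with Monte Carlo sensitivity analysis. A
    synthetic multi-plant cohort generator with known confounding structure
    supports method evaluation when study data are restricted.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
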