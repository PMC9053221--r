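Package: ratelink
Title: Bayesian Rate-Difference Tests and Causal Discovery for Registry Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form Bayesian inference for differences in event rates
    (delta-lambda) between exposure groups in censored time-to-first-event
    registry data, assuming exponentially distributed occurrence times and
    additive per-cause rate increments. The rate-difference posterior is a
    terminating confluent hypergeometric polynomial, and a conditioning-
    invariant version pools a single common rate difference across the strata
    of a conditioning set, preserving statistical power in small cohorts. On
    top of the test sits an order-independent two-step variant of the PC
    constraint-based causal-discovery algorithm that screens all candidate
    cause-outcome pairs and prunes links explained away by conditioning,
    reporting minimal explaining sets and ambiguity sets for perfectly
    correlated exposures. The package also provides registry-style cohort
    handling (observation windows, left truncation, source filters),
    post-hoc reliability checks (calendar-era confounder control, event-timing
    classification, source restriction, person-year frequencies), descriptive
    ICD-10 chapter comparisons, Kaplan-Meier curves, and a synthetic cohort
    generator with planted ground truth.
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
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
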