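Package: lingcast
Title: Probabilistic Cohort-Component Projection of First-Language Speaker
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Estimates probabilistic baseline age structures of small
    speaker populations from repeated census counts (a t-distribution for
    the total and per-cohort negative binomial distributions), derives and
    extrapolates intergenerational transmission rates with the xTFR
    indirect fertility estimator, and runs individual-based stochastic
    cohort-component projections to obtain speaker-number trajectories
    with 80% projection intervals, dormancy risks and threshold years.
    Includes a synthetic census generator (overdispersed counts, random
    rounding to base 5) for calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
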