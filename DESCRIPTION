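Package: tickburden
Title: Sex-Biased Drivers of Tick Burden on Wild Ungulate Hosts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling overdispersed tick burdens on wild hosts with
    negative binomial generalized linear models (log link), forward-backward
    stepwise AIC selection, and deviance partitioning of explained variation
    into pure and shared components of host-individual, host-population and
    environmental factor groups. Includes Turc actual-evapotranspiration
    covariate construction from daily meteorology, cross-population calibration
    validation with equal-count prediction bins, Wald prevalence intervals, and
    a synthetic red deer cohort generator with known ground truth for method
    checking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils,
    withr
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
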