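Package: navclamp
Title: Simulation and Analysis of Whole-Cell Cardiac Sodium Current Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates synthetic whole-cell voltage-clamp recordings of the
    cardiac sodium current (Nav1.5, Nav1.5 with the beta1 subunit, and human
    stem cell-derived cardiomyocytes) including state-dependent antiarrhythmic
    drug block, ohmic leak, capacitive transients and recording noise, and
    analyses them with the standard patch-clamp pipeline: P/-6 leak
    subtraction, current-voltage and conductance-voltage construction,
    Boltzmann and single-exponential fitting, Hill concentration-effect
    curves, series-resistance exclusion rules, and summary-statistics group
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    deSolve,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
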