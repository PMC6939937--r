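Package: zestsim
Title: Bayesian Adaptive Staircases for Stereoacuity Threshold Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring and simulating stereoacuity thresholds with
    adaptive psychophysical procedures. Implements the logistic psychometric
    function with guess and lapse rates, the weighted one-up/one-down
    staircase, grid-based Bayesian adaptive procedures (ZEST with a fixed
    assumed spread, two-dimensional ZEST, Psi, and Psi-marginal variants),
    maximum-likelihood psychometric fitting with deviance goodness-of-fit and
    bootstrap p-values, virtual-observer population generation, and
    Monte-Carlo engines for quantifying threshold bias and precision of
    adaptive procedures, including a percentile sweep that selects the
    assumed spread minimizing |bias x SD| over a population of observers.
License: MIT + file LICENSE
Encoding: UTF-8
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
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
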