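Package: itspower
Title: Simulation-Based Power for Interrupted Time Series Vaccine Impact
    Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the power of an interrupted time series (ITS)
    analysis to detect a vaccine-associated decline in monthly disease
    counts. A seasonal Poisson regression with a Gaussian
    observation-level random intercept (Poisson-lognormal) is fitted to
    the pre-vaccine period by maximum likelihood with Gauss-Hermite
    quadrature; post-vaccine counts are then simulated with a specified
    rate-ratio decline injected as a log-scale linear ramp, the effect is
    re-estimated with a linear-spline ITS model, and power, bias,
    coverage and precision are summarized across replicates, effect
    sizes and baseline lengths. Includes synthetic fixture generators,
    ggplot2 graphics and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    lme4,
    optparse,
    readxl,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
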