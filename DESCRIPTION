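Package: gpsrisk
Title: Smartphone Geolocation Features and Short-Term Risk of Suicidal
    Thoughts and Behaviors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for digital-phenotyping analyses that link smartphone
    GPS mobility to short-term clinical risk in intensive longitudinal
    studies. Converts raw GPS fix streams into daily homestay, location
    entropy, and distance traveled; aggregates them into Wednesday-aligned
    weekly panels with within-person and between-person standardized
    terms; fits random-intercept logistic regressions by maximizing the
    exact marginal likelihood with adaptive Gauss-Hermite quadrature;
    and evaluates predictive accuracy with leave-future-out and
    between-person designs using Mann-Whitney AUC and bootstrap
    confidence intervals. A synthetic cohort generator with known ground
    truth supports testing and power analysis when raw study data cannot
    be shared.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    geosphere,
    lme4,
    pracma,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
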