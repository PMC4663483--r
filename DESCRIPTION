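Package: mortwear
Title: Duration of Ungulate Mortality Events from Tooth Microwear Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies the duration of ungulate mortality events from the
    variability of dental microwear scratch densities across individuals in an
    assemblage. Per-sample standard deviation (SD) and coefficient of
    variation (CV) of scratch density place each sample in a two-dimensional
    plane which a three-class Gaussian naive-Bayes classifier partitions into
    regions for short events (one month to one season), long-continued events
    (four months to a year), and two short events separated by a season.
    Includes a seasonal-diet simulator for generating calibrated synthetic
    training data, admissibility rules for extracting scenario-labelled
    training sub-samples from dated death records, boundary curves,
    classification-uncertainty heat maps, probability isolines of the total
    mixture density, and expected-total-error estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
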