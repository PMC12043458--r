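Package: ofsgrain
Title: Micronutrient and Health Impact Assessment for Organic Fertilizer
    Substitution in Wheat
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for evaluating agronomic
    biofortification of wheat through partial substitution of chemical
    nitrogen fertilizer with organic fertilizer (OFS). Provides validated
    plot-level field-trial data structures with CSV input/output, a
    calibrated synthetic generator for multi-site randomized trials,
    closed-form one-way ANOVA with Fisher's LSD compact-letter display and
    Pearson correlation, nutritional yield (adults fed per hectare per
    year), phytate-to-mineral molar-ratio bioavailability indices, and an
    ex-ante disability-adjusted life year (DALY) model of the health and
    economic impact of increased grain iron and zinc under population
    coverage scenarios.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
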