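Package: urbanfrailty
Title: Urban-Quality Accessibility Index, Frailty and Nutrition Scoring, and
    Calibrated Synthetic Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the quality of the urban environment
    relates to frailty and to nutritional and blood markers in older adults.
    Computes a raster-based urban-quality summary index from Euclidean
    distances to seven types of urban facility, scores clinical frailty with
    the five-domain Frailty Trait Scale (FTS-5) and nutritional risk with the
    CONUT score, and reproduces the quartile-stratified group comparisons and
    Spearman correlation panels used in geospatial frailty studies. Includes a
    synthetic city-and-cohort generator (Poisson facility layers, Gaussian
    copula labs, logistic frailty model) calibrated so that downstream
    analyses can be tested without access to any real cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
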