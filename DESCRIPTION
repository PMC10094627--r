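Package: aromakey
Title: Volatile Flavor Compound Profiling and Key Odorant Screening for GC-MS Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for non-targeted volatile flavor
    compound (VFC) analysis of GC-MS peak tables, developed around the aroma
    chemistry of Guangdong black teas. Provides internal-standard
    semi-quantification of peak areas, chemical-class composition profiling,
    a from-scratch NIPALS partial least squares discriminant analysis
    (PLS-DA) with cross-validated Q2, variable importance in projection
    (VIP) scores and SIMCA-style permutation validation, odor activity
    value (OAV) screening of differential odorants, hierarchical-clustering
    heat-map export, and a calibrated synthetic peak-table generator that
    emulates the statistical structure of multi-district tea surveys.
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
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
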