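Package: leadrisk
Title: Risk Classification of Dietary Lead in Vegetables by Spectral Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for grading the dietary risk of lead contamination in
    vegetables from censored monitoring data. Computes the Nemerow integrated
    pollution index, the hazard index at high (P95) exposure, and the margin of
    exposure at median (P50) exposure for every region-by-food combination,
    applies the GEMS/FOOD limit-of-detection substitution rule to non-detects,
    and assigns discrete ordered risk levels by spectral clustering with
    data-driven selection of the kernel width and cluster count via the
    Calinski-Harabasz index. Includes a synthetic-data generator with planted
    risk tiers for validation, and broom-style tidiers and ggplot2 plots for
    the fitted objects.
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
    withr,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
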