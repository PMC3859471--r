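Package: famagg
Title: Familial Aggregation Analysis of Binary Phenotypes on Population
    Genealogies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tests for familial aggregation of a binary phenotype (here, low
    body mass index) on deep multi-generation genealogies. Implements the
    Genealogical Index of Familiality (GIF) and its distant-relative variant
    with empirical significance from matched-control resampling, cohort-
    standardized relative risks in first- through seventh-degree relatives
    with exact binomial and Poisson-ratio confidence intervals, and discovery
    of high-risk pedigrees whose founder descendancies carry a significant
    excess of cases. A liability-threshold genealogy simulator with
    driver's-license-style phenotype ascertainment makes every stage testable
    without access to restricted population databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
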