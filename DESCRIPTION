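Package: wmiscan
Title: Weighted Mutual-Information Epistasis Scanning in Stratified Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exhaustive two-SNP epistasis analysis of quantitative traits
    (blood pressure) within physiologically defined subpopulations: composite
    3x3 genotype tables, weighted variance decomposition into marginal and
    interaction components, a weighted mutual-information (WMI) interaction
    score with chi-square (4 df) significance testing, broad-sense
    heritability estimation as the plateau of relative genetic variance over
    WMI (polynomial, Boltzmann and Gaussian fits), two-SNP case-control
    prevalence analysis of hypertension, and interaction-network topology
    characterization (power-law plus Poisson-residual fits, hub ranking).
    Includes a synthetic-cohort generator with planted epistatic effects so
    the whole pipeline is testable end to end, and readers for simple TSV and
    PLINK-style ped/map genotype files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    igraph,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    generics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
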