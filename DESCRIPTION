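Package: riailmap
Title: Quantitative Genetics for Recombinant Inbred Advanced Intercross Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for quantitative trait locus (QTL)
    mapping in two-parent recombinant inbred advanced intercross line (RIAIL)
    panels such as the C. elegans N2xCB4856 collections. Simulates advanced
    intercross breeding designs with recombination, drift and locus-specific
    incompatibility selection; calls two-state genotypes from SNP intensity
    data by EM mixture modelling with allele-frequency filtering and
    hidden-Markov-model imputation; converts large-particle-sorter event files
    into fecundity and body-size trait matrices (including bubble/animal
    classification); and maps traits with a correlation-based LOD statistic,
    iterated conditional scans, joint-permutation false-discovery-rate
    thresholds, 1.5-LOD-drop confidence intervals, and broad-sense
    heritability decomposition from repeat measures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    lme4,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
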