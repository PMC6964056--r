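Package: gvcomp
Title: Genomic Dissection of Additive, Dominance, Epistatic and Maternal Variance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-kernel GBLUP variance-component analysis for populations of
    full- and half-sib families. Builds additive, dominance and epistatic genomic
    relationship matrices under Hardy-Weinberg-equilibrium (HWE) and natural and
    orthogonal interactions (NOIA) parameterizations, fits linear mixed models by
    average-information REML with a genomic-homozygosity covariate for directional
    dominance, compares nested models with boundary-corrected mixture chi-square
    likelihood-ratio tests, rescales variance components to a common reference
    population, and quantifies inbreeding depression. Includes a gene-dropping
    simulator for reciprocal partial-factorial mating designs so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
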