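Package: methkin
Title: Family-Based Genetic Analysis of DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Heritability and genetic regulation of DNA methylation in
    extended pedigrees. Parses PED-style pedigrees and builds additive
    genetic relationship matrices by the tabular recursion; applies a
    methylation-array quality-control chain (sample call rate, coefficient
    of variation, probe call rate, beta-value variation, Monte-Carlo
    Lilliefors normality screen, X-linked exclusion); fits polygenic
    variance-component models by maximum likelihood with boundary-mixture
    likelihood-ratio tests for heritability; runs cis measured-genotype
    association of SNP dosages with methylation and methylation-as-covariate
    tests for obesity traits; corrects for multiple testing by Bonferroni,
    Sidak, the Li-Ji effective number of tests and tail-area FDR; and ships
    a family-structured synthetic study generator so the whole pipeline is
    testable end to end.
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
    readr,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    nortest,
    yaml,
    optparse,
    vcfR,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
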