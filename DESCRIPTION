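Package: snppop
Title: Population Genetics of SNP-Chip Genotypes: QC, Linkage
    Disequilibrium, Structure and Effective Population Size
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the classic SNP-array population-genetics workflow on
    small livestock cohorts: PED/MAP input and output, sample- and
    marker-based quality control (call rate, minor allele frequency, exact
    Hardy-Weinberg test), EM estimation of two-locus haplotype frequencies
    with D, D' and r2, windowed LD pruning, observed and expected
    heterozygosity, method-of-moments inbreeding and pairwise IBD (PI_HAT),
    AMOVA with a permutation null, Weir-Cockerham FST, genomic relationship
    matrix PCA, an EM admixture model with cross-validated choice of K,
    distance-binned LD decay, and LD-based historical effective population
    size via Sved's recombination mapping. Includes forward Wright-Fisher,
    Balding-Nichols, pedigree gene-dropping and admixture simulators with
    recorded truth so every estimator is testable by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
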