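Package: inbreedNe
Title: Pedigree and Genomic Inbreeding Coefficients and Effective
    Population Size in Structured Populations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to compare pedigree-based and marker-based inbreeding
    coefficients and the effective population sizes derived from them in
    populations bred over discrete generations. Implements the
    Meuwissen-Luo pedigree inbreeding recursion, five genomic-relationship
    -matrix diagonal estimators (Nejati-Javaremi, Li & Horvitz, VanRaden 1
    and 2, Yang), sliding-window runs-of-homozygosity detection with
    PLINK-style parameters, reference-generation adjustment of estimators,
    individual increases in inbreeding and realised effective population
    size per generation, founder-distance estimates, and Pearson
    correlation reports. A gene-dropping breeding simulator with
    true-identity-by-descent tracking emulates a divergent selection
    design (founder lines, panmictic burn-in, random-mating phase, two
    closed selected lines) and provides ground truth for validation.
    Genotypes are read and written in PLINK text and binary formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
biocViews: Genetics, SNP, QualityControl, Software
RoxygenNote: 7.3.3
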