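Package: trioRareVar
Title: Trio-Based Association Tests for Grouped Rare Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Family-based association tests for groups of rare (and common)
    variants in a gene region using case-parents trios. Implements the
    largest single-variant transmission disequilibrium test, a multivariable
    score test, the combined TDT, and a likelihood-ratio test built on a
    random-effects mixture model for per-variant transmission probabilities,
    all with a within-family permutation null that is robust to population
    stratification. Includes a trio cohort container built on
    SummarizedExperiment, VCF/PED and TSV readers, and a simulation
    framework for evaluating type I error and power under configurable
    regional architectures (functional fraction, effect sizes, protective
    variants, common/rare mixtures, and two-population stratification).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, SNP, GeneticVariability, StatisticalMethod
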