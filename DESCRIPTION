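Package: popadmix
Title: Population Structure, Ancestry Decomposition, and Admixture-LD Dating
    for SNP Genotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for genome-wide population-structure analysis of diploid
    biallelic SNP genotypes: PLINK-format input and output, quality control
    and sliding-window LD pruning, identity-by-state distances with classical
    multidimensional scaling, variance-normalized principal component
    analysis with iterative outlier trimming, likelihood-based unsupervised
    ancestry decomposition with cross-validation over the number of
    components and between-component FST, dating of admixture events from
    the exponential decay of admixture linkage disequilibrium with genetic
    distance, and conversion of FST to drift divergence time.  A
    Balding-Nichols ancestry-tract simulator generates synthetic cohorts
    with known admixture proportion and time for validation, and a
    configuration-driven pipeline runs the full analysis reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
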