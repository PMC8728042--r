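Package: pedrec
Title: Pedigree-Based Crossover Detection and Recombination Landscape Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing recombination landscapes in
    multigenerational breeding pedigrees genotyped by shallow
    genotyping-by-sequencing (GBS). Provides pedigree-aware genotype
    calling from allele read depths with Mendelian priors, a two-state
    inheritance hidden Markov model that detects crossovers in
    parent-offspring duos with switch-error correction, construction of
    sex-averaged, sex-specific and introgression-dosage-specific genetic
    maps, and the associated statistical battery: chi-square tests for
    heterochiasmy in 1-Mb windows and genome-wide, Poisson-regression
    deviance goodness-of-fit tests for crossover interference, and tests
    for recombination suppression inside wild-introgression segments.
    A meiosis simulator with gamma-renewal crossover interference,
    sex-specific map scaling and introgression suppression generates
    GBS-like data with known ground truth so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
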