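Package: introgressr
Title: Admixture, Hybrid Classification and Diversity Statistics for
    Microsatellite and Mitochondrial Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying hybridization and introgression between
    two closely related taxa from codominant microsatellite genotypes and
    aligned mitochondrial sequences.  Provides readers and writers for
    STRUCTURE and GENEPOP text formats, per-population diversity statistics
    (observed and expected heterozygosity, rarefied allelic richness),
    Weir-Cockerham FST with permutation tests, principal component analysis
    of population allele frequencies with randomization significance, a
    Bayesian admixture model with correlated allele frequencies fitted by
    Gibbs sampling (with learning samples, 90% credible intervals and
    Evanno delta-K model selection), simulation of F1/F2/backcross hybrid
    genotypes from parental pools, admixture-proportion bin classification
    calibrated on simulated crosses, Nei haplotype and nucleotide diversity
    for mitochondrial alignments, and a synthetic-data generator that
    emulates a two-species microsatellite survey end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
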