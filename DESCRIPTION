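Package: gdassess
Title: Genomic Diversity Metrics for Conservation Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes population genomic diversity metrics from diploid
    genotype data for use in conservation assessments: windowed Watterson's
    theta, nucleotide diversity and Tajima's D, individual and population
    heterozygosity, and runs of homozygosity (ROH) called with a two-state
    hidden Markov model and summarized as F_ROH fractions. Projects
    heterozygosity loss under genetic drift over a 100-year horizon and
    assigns genetic Red List categories from the projected loss rate,
    effective population size floors, and a relative-heterozygosity
    comparison against threatened relatives. Also computes the IUCN Green
    Score and a genetic-diversity-corrected variant. Includes a Kingman
    coalescent simulator with infinite-sites mutation for generating
    genotype fixtures at known theta, with optional injected autozygous
    tracts, so every estimator can be validated against closed-form
    expectations without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
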