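Package: camoseq
Title: Simulation-Based Assessment of Short-Read Mapping in High-Homology Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how pseudogenes and paralogous regions degrade
    short-read mapping and variant calling across a clinical gene panel.
    Generates synthetic reference panels with homologous tracts of controlled
    identity, simulates truth-labelled paired-end reads from diploid genomes
    built over multi-population genotypes, maps them with a deterministic
    seed-and-extend paired-end aligner, computes k-mer mappability and
    BLAST-like homology flags, calls camouflaged (low-depth) regions, measures
    population differentiation (Weir-Cockerham FST, genotype PCA) against
    coverage, and evaluates pseudogene-aware variant-rescue strategies
    (elongated inner distance, lowered mapping-quality cutoffs, and reference
    masking with ploidy-4 genotyping).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils,
    Biostrings,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
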