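Package: pnpstools
Title: Polymorphism-Based Selection Analyses for Clonal Polyploid Lineages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the efficacy of purifying selection between
    asexual polyploid lineages and their sexual relatives using transcriptome
    SNP data. Implements effect-classified, depth-conditioned pN/pS summaries
    with Nei-Gojobori (1986) site counting, allele-balance ploidy inference
    for diploid versus triploid samples, genotype-identity clonality metrics,
    genotype-pattern partitioning of SNPs into candidate-novel and ancestral
    classes, a likelihood-ratio test for unequal pN/pS between SNP classes,
    pairwise NG86/Jukes-Cantor dN/dS, and a synthetic-data generator that
    emulates a hybrid-origin triploid apomict plus a diploid outcrossing
    population with read-count-backed genotype calls and truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
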