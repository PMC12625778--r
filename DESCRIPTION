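Package: sweepomics
Title: Selective-Sweep Scanning and Multiomic Integration for Domestication Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrative analysis of domestication genomics:
    composite-likelihood-ratio (CLR) selective-sweep scanning on population
    genotypes under a star-genealogy hitchhiking model, windowed Weir-Cockerham
    FST and nucleotide diversity, dynamic-time-warping comparison of
    developmental expression time courses between breeds (progression-advanced
    scores and differentially progressing genes), differentially methylated
    region calling from replicated bisulfite counts, variant consequence
    classification against gene models, and permutation/hypergeometric
    enrichment statistics linking the genomic, transcriptomic and epigenomic
    layers. Includes synthetic-data generators with ground-truth manifests for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
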