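Package: geneContext
Title: Conserved Gene-Neighborhood and Genomic-Context Analysis for
    Prokaryotic Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative-genomics analysis of gene
    neighborhoods in prokaryotic genomes. Reads NCBI PTT protein tables
    and a GenBank flat-file subset, extracts query-centered gene windows,
    infers putative co-transcribed blocks (directons) from strand and
    intergenic-distance rules, clusters neighbor proteins into families
    by single-linkage over pairwise local-alignment similarity, detects
    partner families conserved across genomes with a permutation-based
    significance estimate, runs an iterative profile search with
    reciprocal validation against profile corruption, annotates protein
    alignments with physicochemical consensus class codes, and scans for
    degenerate class-coded motifs. Includes a synthetic-genome generator
    that plants protein families, operons and contextual associations
    with full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    igraph,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: ComparativeGenomics, Genetics, SequenceMatching, Alignment
RoxygenNote: 7.3.3
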