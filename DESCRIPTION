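Package: kccomp
Title: Comparative Genomics Curation of the Potassium-Channel Gene Family
Version: 0.9.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale comparative-genomics toolkit for curating large gene
    families across vertebrate genomes, built around the potassium (K-)
    channel family of songbirds. Provides a curated gene registry with
    reconciliation arithmetic, gene-map/sequence/tree containers with
    standard-format I/O (GFF3, FASTA, FASTQ, Newick), Smith-Waterman and
    Needleman-Wunsch alignment with a seed-and-extend secondary-locus
    search, synteny-based ortholog/duplication/allele/pseudogene
    classification, Dollo parsimony gain/loss reconciliation,
    quality-masked allelic-variant and indel calling, Nei-Gojobori (NG86)
    dN/dS estimation with a two-stage high-selective-pressure screen,
    PROSITE-style motif fingerprint scanning, semi-quantitative expression
    scoring for song-system nuclei, a ground-truthed multi-species genome
    simulator, and a pipeline orchestrator with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Matrix,
    jsonlite,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
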