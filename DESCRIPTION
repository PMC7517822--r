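Package: dgrscan
Title: Detection and Characterization of Diversity-Generating Retroelements in Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Mines bacterial genome assemblies for diversity-generating
    retroelements (DGRs). Anchors on reverse-transcriptase (RT) genes, searches
    the surrounding 10-kbp region for near-identical repeat pairs, applies the
    adenine-mutagenesis signature (mismatches concentrated at template-repeat
    adenines and at 1st/2nd codon positions of the variable region) to separate
    template repeats (TR) from variable regions (VR), assembles RT-TR-VR
    cassettes, maps dispersed remote variable proteins by TR homology, clusters
    paralogs CD-HIT-style, and inventories mobile-element annotations in
    cassette neighborhoods. Includes a synthetic-genome generator that plants
    cassettes, remote targets, transposases and decoy repeats with a
    machine-readable truth table, so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
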