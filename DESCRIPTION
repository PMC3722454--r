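Package: ampliPhy
Title: Degenerate Primer Design, In-Silico PCR and Marker-Gene Phylogeny
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for marker-gene surveys built around degenerate
    oligonucleotide primers: detects conserved blocks in a multiple
    alignment of homologous genes and emits IUPAC consensus primers,
    predicts PCR products of degenerate primer pairs on template
    sequences (in-silico PCR with mismatch and 3'-anchor control),
    computes pairwise global-alignment percent identity matrices over
    amplified fragments, and builds neighbor-joining trees with
    bootstrap supports. Ships the six-primer panel targeting the bile
    salt hydrolase (bsh) gene of bifidobacteria and a Jukes-Cantor
    simulator that plants primer footprints on a known phylogeny so the
    whole workflow is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
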