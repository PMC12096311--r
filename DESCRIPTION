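Package: svrefine
Title: Base-Pair Resolution and Benchmarking of Structural Variants in
    Repetitive Genomic Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Consolidates redundant structural-variant (SV) calls between two
    genome assemblies into SV regions, anchors region boundaries with uniquely
    aligned flanking sequences (UAS), resolves breakpoints at base-pair
    resolution by cataloguing and similarity-matching repeat copies, classifies
    events into insertions, deletions, inversions and substitutions, and scores
    call sets against a benchmark under strict or relaxed matching. Includes a
    seeded synthetic genome-pair simulator that plants SVs in configurable
    repeat landscapes (tandem arrays, dispersed copies, inverted repeats,
    fold-back clusters) with exhaustively enumerated breakpoint-ambiguity
    intervals, and breakpoint-context statistics (regional relative rates,
    AT-content of breakpoint windows).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    data.table,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
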