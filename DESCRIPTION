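Package: g4topo
Title: Dual-Method G-Quadruplex Detection and Genomic Topography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects putative G-quadruplex (G4) forming sequences on both
    strands of a genome with two complementary methods (a consensus-motif
    regular expression and a G4Hunter-style sliding-window G-richness
    score), reconciles the two call sets under fractional-overlap rules,
    and analyses the genomic topography of the resulting catalog:
    densities over genomic subcompartments, strand-aware metaprofiles
    around transcription start/end sites and splice sites with
    Monte-Carlo confidence bands, circular-chromosome strand asymmetry
    around the replication origin with a binned GC-skew co-track, and
    G-run/loop structural decomposition.  A synthetic-genome generator
    plants consensus motifs with configurable promoter/terminator/splice
    enrichment, GC skew, and leading-strand bias, so every stage is
    testable against ground truth without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
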