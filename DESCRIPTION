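Package: parchmentid
Title: Species Identification and Authentication of Parchment DNA from
    Mitochondrial Capture Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies the source species of parchment (prepared animal
    skin) from mitochondrial capture sequencing reads.  Implements the
    full desk-side workflow: merging of overlapping read pairs,
    modified-Mott quality trimming, competitive mapping of merged reads
    against a panel of candidate mitochondrial reference genomes with
    tie exclusion and coordinate-based PCR duplicate removal, consensus
    mitogenome construction with depth and breadth statistics, a
    four-criterion sequential authentication gate, Kimura-80/UPGMA
    phylogenetic placement with bootstrap support, and human
    contamination profiling by read length.  A synthetic-read generator
    emulating degraded parchment libraries makes the whole pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
SystemRequirements: MAFFT (multiple sequence alignment; must be on PATH)
Config/testthat/edition: 3
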