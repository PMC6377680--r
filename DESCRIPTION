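Package: mtbreak
Title: Mitochondrial DNA Deletion Breakpoints, Junction Repeats, and
    Copy-Choice Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects large deletions and likely duplications of the circular
    mitochondrial genome from deep-sequencing reads via gapped (split)
    alignments, filters and deduplicates the supporting evidence, clusters
    breakpoint pairs into unique segment calls, estimates per-call
    heteroplasmy, and characterizes the junctions: longest exact direct
    repeat, imperfect-repeat 5'/3' retention directionality, cytosine-rich
    motif tables, randomized-breakpoint null ensembles and repeat-length
    enrichment, and cross-dataset repeat-pattern overlap. Includes a
    synthetic-data generator that plants direct or imperfect repeat pairs in
    a circular reference and forms deletions by copy-choice recombination
    (one repeat copy retained, the intervening sequence and the other copy
    lost), simulating junction-spanning reads with substitution errors, PCR
    duplicates and a configurable wild-type/deleted molecule mixture, with
    full ground truth for pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
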