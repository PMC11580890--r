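Package: svdisrupt
Title: Scoring Structural Variant Disruption of 3D Genome Folding at
    Regulatory Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: In-silico mutagenesis of structural variants against a
    sequence-to-contact-map predictor. Builds ~1 Mb prediction windows
    around deletions, duplications, inversions and complex variants,
    constructs reference/alternate allele sequence pairs, aligns the
    resulting contact frequency maps by padding and masking, and scores
    disruption globally (1 - Spearman correlation, MSE) and per bin.
    Per-bin disruption tracks can be weighted towards regions of
    interest such as promoter-anchored chromatin loops (CREints) derived
    from PLAC-Seq data. Includes loop filtering and redundancy merging,
    variant-loop pairing with window shifting, a multi-criterion variant
    prioritization engine, 1 Mb-bin enrichment tests, cohort rank tests,
    tiled 1-bp deletion scans, a deterministic motif-based surrogate
    predictor so the whole pipeline runs without trained network
    weights, and a synthetic fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
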