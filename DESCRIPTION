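Package: epiremod
Title: Multiscale Epigenome Remodeling Statistics for TF-Driven Reprogramming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative machinery for studying multiscale epigenome
    remodeling during transcription-factor-driven cell-fate conversion.
    Implements enhancer-gene pair (EGP) linking from single-cell multiome
    data with metacell aggregation and GC/accessibility-matched empirical
    nulls, per-gene TF linkage scoring with exact hypergeometric enrichment,
    Hi-C feature statistics (contact-probability decay, matrix balancing,
    A/B compartments and compartment strength, insulation-score TAD boundary
    calling, rescaled TAD aggregation, aggregate peak analysis at anchor
    pairs, per-pair contact scores), CpG methylation filtering and
    aggregation at regulatory elements, peak-set overlap classification and
    motif enrichment, and a seeded synthetic-data generator that plants
    ground truth (compartments, TADs, loops, linked peak-gene pairs,
    hypomethylated dips) so every stage is testable end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    Matrix,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
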