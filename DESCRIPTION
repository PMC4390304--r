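Package: colocperm
Title: Co-Localization Enrichment Tests for Genomic Interval Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Observed-versus-expected (O/E) overlap enrichment between
    genomic interval tracks, with Monte Carlo permutation null models that
    exactly preserve per-chromosome segment-length and inter-segment gap
    distributions, confounder-restricted randomization for conditioning on
    open-chromatin (or other) tracks, case-control excess enrichment
    difference (EED) tests, peak-centered density profiles, and a position
    weight matrix screen for variant-induced motif disruption with exact
    score p-values.  Includes a synthetic-data generator that plants known
    enrichment, confounder-mediated association, and motif-disrupting
    variants so every stage of the pipeline can be validated against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    graphics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
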