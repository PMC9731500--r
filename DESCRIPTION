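Package: meclipr
Title: Single-Nucleotide m6A Site Calling from Crosslink-Induced C-to-T
    Conversions, with Downstream RNA Quantification Utilities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects N6-methyladenosine (m6A) sites at single-nucleotide
    resolution from antibody-based eCLIP libraries, exploiting the
    diagnostic C-to-T conversion that reverse transcription introduces
    immediately 3' of a methylated adenosine. Provides per-position
    pileups from aligned reads, RAC-motif and frequency-window filtering,
    input-library subtraction, confidence tiers, and multi-replicate
    consensus reporting. Includes a seed-deterministic read simulator
    with planted ground-truth sites for end-to-end validation, plus
    downstream quantification helpers: percent-input RIP recovery,
    delta-delta-Ct chromatin association, log-linear doubling-time fits,
    peak proximity and metaprofiles around sites, and classification of
    paired differential-expression contrasts into loss-of-function and
    antimorph categories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
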