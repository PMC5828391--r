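Package: satfrag
Title: Fragment-Level Occupancy Profiling of Centromeric Alpha-Satellite Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of CENP-A/B/C (CCAN) occupancy on tandem
    alpha-satellite repeat arrays from paired-end sequencing of
    salt-fractionated, antibody-targeted chromatin. Provides a truth-labelled
    synthetic data generator for 340/342-bp alpha-satellite dimeric units with
    CENP-B boxes, direct fragment-length inference by overlap merging of read
    pairs, exhaustive end-to-end ungapped mapping to repeat references,
    triplicated-consensus coverage folding onto the middle dimer, CENP-B box
    motif scoring and density, spike-in calibrated fold enrichment over an IgG
    control, salt-fraction percent recovery, motif-enrichment correlation, and
    per-dimer footprint orientation/symmetry classification.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
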