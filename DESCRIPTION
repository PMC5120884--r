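Package: wormstate
Title: Locomotor State, Calcium Transition, Optogenetic Epoch, and
    Subtractive Enrichment Analysis for C. elegans Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for quantifying neuromodulation of
    Caenorhabditis elegans locomotion. Segments tracked trajectories into
    forward/reversal/pause bouts and computes propensity, initiation
    frequency, duration and velocity metrics; quantifies ratiometric
    GCaMP/RFP calcium dynamics around directional transitions
    (acceleration/deceleration rates, calcium rise/decay slopes and their
    correlation); segments free-crawling trajectories into runs and turns
    and compares run statistics across optogenetic stimulation epochs; and
    implements a subtractive FACS-sorted-cell transcriptome enrichment
    pipeline (median-of-ratios normalization, negative-binomial testing,
    Benjamini-Hochberg FDR, enrichment filters, cross-genotype set
    subtraction and marker validation). A synthetic-data module generates
    all four input kinds with known ground truth so every stage is
    testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
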