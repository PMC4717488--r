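Package: ribofidelity
Title: Reading-Frame Fidelity, Non-AUG Initiation and Codon Dwell Metrics
    from Ribosome Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize translational fidelity from ribosome
    profiling data in yeast-like genomes. Filters ribosome-protected
    fragments, assigns P-sites by a fixed 5' offset, profiles reading-frame
    usage in ~300-nt windows along each ORF, calls per-ORF translational
    ambiguities and localizes frameshift transition points, scans 5'
    leaders for in-frame near-cognate (non-AUG) initiation candidates with
    read-support scoring, computes per-codon ribosome dwell metrics (codon
    occupancy and ribosome residence time) at the E, P and A sites, and
    derives codon-level translation-efficiency indices (CAI, tAI, nTE)
    together with wobble-decoding classification and arginine-codon usage
    ranking. A seeded footprint simulator with per-read ground truth
    supports validation of every analysis step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
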