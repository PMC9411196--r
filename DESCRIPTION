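Package: codonDecay
Title: Codon Optimality-Mediated mRNA Decay from tRNA Modification
    Profiling, Metabolic-Labeling Decay Courses, and Ribosome Profiling
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the tRNA/mRNA axis in differentiating cell
    types. Implements per-position tRNA variant and reverse-transcriptase
    fall-off profiling from SAM alignments (CIGAR/MD walking), reference
    collapsing and isodecoder/anticodon read counting, spike-in-normalized
    mRNA half-life estimation by least-absolute-deviations exponential
    fitting with censoring, Codon Stabilization Coefficients, synonymous
    codon-bias binning with a Kruskal-Wallis group test, and windowed
    per-codon ribosome pause scores normalized by matched RNA-seq. Seeded
    synthetic-data generators emulate each sequencing experiment
    (modification-dependent mismatch/stop signatures, exponential decay
    with constant spike-in mass, codon-dependent ribosome dwell) so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
biocViews: Transcriptomics, Sequencing, RNASeq, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
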