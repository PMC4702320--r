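Package: donorSAE
Title: Donor Splice Site Prediction from Short Motifs via Di-Nucleotide
    Association and Sum-of-Absolute-Error Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts donor (5') splice sites from short, position-aligned
    sequence motifs without numeric encoding of the sequence data.
    Implements a position-pair nucleotide association measure used to
    choose a compact modeling window around the conserved GT
    di-nucleotide, and a sum-of-absolute-error (SAE) classifier that
    scores candidate sites from class-conditional di-nucleotide
    probabilities estimated on true and false splice-site training sets.
    Includes weight-matrix (WMM) and first-order Markov (MM1) log-odds
    baselines, ROC analysis with the Hanley-McNeil standard error,
    precision-recall analysis with Davis-Goadrich interpolation,
    redundancy and similarity preprocessing, stratified threshold
    estimation by cross-validation, and a synthetic motif/gene generator
    with controllable positional composition and pairwise couplings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
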