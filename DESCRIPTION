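Package: eukinet
Title: Detection of 5EU-Labeled Nascent RNA from Raw Nanopore Signal and
    Downstream RNA Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies individual direct-RNA nanopore reads as
    5-ethynyl-uridine (5EU) labeled or unlabeled straight from the raw
    current trace, with no basecalling or alignment, using a compact
    convolutional plus bidirectional-GRU neural network trained with
    chromosome-holdout splits, balanced sampling, gradient accumulation and
    AUROC-based early stopping. Includes raw-signal container I/O
    (multi-read fast5 dialect and a portable fixture format), the standard
    per-read preprocessing (head crop, length filters, med-MAD
    normalization), a k-mer pore-model squiggle simulator with ground-truth
    5EU labels for end-to-end validation, classification metrics with
    stratified evaluation, and transcript-level kinetics: modification
    fractions, relative modification increase between conditions, and
    first-order half-life estimates from modified/unmodified read counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    rhdf5,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
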