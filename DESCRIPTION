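Package: panelcnv
Title: Exon Copy-Number Variant Detection in Targeted Sequencing Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Read-depth detection of whole-exon deletions and duplications
    in exon-targeted next-generation sequencing panels. For each test
    sample a set of well-correlated reference samples is selected from the
    batch, a beta-binomial model is fitted to the test counts against the
    aggregated reference, and a three-state hidden Markov model with
    distance-dependent transition probabilities is decoded to call
    copy-number segments with log10 Bayes factors and quality-control
    annotations. Includes a synthetic coverage-matrix generator, spike-in
    and binomial read-resampling simulation studies for benchmarking
    sensitivity and specificity, per-call visualisations, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
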