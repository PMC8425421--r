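Package: tssformer
Title: Interpretable Attention Networks for Bacterial Transcription Start
    Site Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how attention-based sequence models learn
    bacterial promoter architecture. Provides a segment-recurrent,
    convolution-augmented multi-head attention network that labels
    transcription start sites (TSSs) along a genome, utilities for curating
    TSS annotations from multiple noisy experimental sources, and an
    interpretability toolkit that characterises each attention head by its
    positional focus and preferred sequence motif. A synthetic-genome
    generator with planted promoter elements (-10 and -35 boxes, optional
    position-specific upstream box) makes every stage testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
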