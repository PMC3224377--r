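Package: nucleoflex
Title: Sequence-Dependent DNA Physical Properties, MNase Digestion Bias
    and Nucleosome Positioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools linking sequence-dependent physical properties of naked
    DNA to micrococcal nuclease (MNase) digestion patterns and nucleosome
    positioning. Implements dinucleotide/tetramer-level elastic models of
    DNA (6x6 helical-parameter stiffness matrices, pure stiffness constants
    and their product k_total), harmonic nucleosome deformation energy over
    147 bp windows, and energy-based prediction of nucleosome-enriched and
    depleted regions. Provides MNase-seq processing from mapped read
    intervals: per-base coverage with reads-per-million normalization and
    duplicate capping, cut-site tetramer extraction and enrichment
    statistics, low-coverage-region detection, naked-DNA bias correction,
    FFT-smoothed nucleosome calling and well-positioned/fuzzy
    classification, and metagene aggregation around TSS/TTS anchors. A
    seeded synthetic-digestion generator emits ground-truth genomes,
    nucleosome maps and sequence-biased reads for desk-scale validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    methods,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
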