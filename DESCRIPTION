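Package: netLTP
Title: Network-Level LTP Analysis for High-Density Microelectrode Array Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying network-level long-term potentiation (LTP)
    from evoked field-potential recordings on high-density CMOS microelectrode
    arrays (64x64 grid, 42 um pitch, 14 kHz). Provides a synthetic session
    generator with layer-structured evoked waveforms and ground truth, stimulus
    -aligned preprocessing (zero-phase Butterworth filtering, artifact blanking,
    epoching), fEPSP slope and input/output-curve calibration, normalized
    potentiation time courses and layer plasticity percentages, PCA + k-means
    waveform classification with confusion-matrix scoring, latency-based
    temporal clustering with recruitment statistics, and two-dimensional kernel
    current source density (kCSD) estimation with cross-validated
    regularization and sink/source quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    pracma,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
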