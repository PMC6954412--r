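Package: peldor
Title: Orientation-Selective PELDOR/DEER Simulation and Distance Analysis
    for Spin-Labelled Nucleic Acid Duplexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pulsed electron-electron double resonance (PELDOR,
    also known as DEER) spectroscopy of nitroxide spin-label pairs on DNA
    and RNA double helices. Builds nitroxide axis frames from multi-model
    structure files or frame tables, generates synthetic label-pair
    ensembles on ideal A- and B-form helices with configurable distance
    and orientation fluctuations and syn/anti conformer states, computes
    orientation-selective PELDOR time traces at X- and G-band from g- and
    hyperfine-tensor physics with rectangular-pulse excitation profiles,
    and processes time traces into distance distributions by homogeneous
    three-dimensional background correction and non-negative Tikhonov
    regularization with L-curve selection of the regularization parameter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    pracma,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    jsonlite
Config/testthat/edition: 3
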