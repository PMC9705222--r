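Package: quadcal
Title: Quadrature Calibration and Complex-Signal Reconstruction for
    Full-Range Optical Coherence Tomography
Version: 0.1.0
Authors@R:
    person("Jules", "Moreau", email = "jmoreau@quadcal.dev", role = c("aut", "cre"))
Description: Tools for full-range swept-source optical coherence tomography
    (FR-OCT) with passive quadrature demultiplexing. Provides a forward
    simulator of a dual-channel interferometric detection chain with
    configurable chromatic (wavelength-dependent) and RF (depth-dependent)
    amplitude and phase imbalances, a calibration pipeline that estimates the
    imbalance vectors directly from mirror measurements at multiple depths,
    quadrature reconstruction of the complex interferogram, and quantitative
    mirror-artifact extinction metrics. Includes delimited-text persistence,
    a command-line interface, and a sampling-density study harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
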