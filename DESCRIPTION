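Package: dectmix
Title: Multimodal Multi-Material Decomposition for Dual-Energy CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Material decomposition for dual-energy computed tomography beyond
    the classical three-material limit. Implements the linear two-energy
    attenuation mixing model with volume conservation, a closed-form
    three-material solver, a histology-anchored correction that recovers the
    volume fractions of materials invisible to histology (iodinated contrast
    agent, formalin fixative) by constrained least squares in the attenuation
    plane, calibration of basis-material attenuation coefficients from aqueous
    dilution series and from specimen groups via global optimization of
    multiplicative correction factors, and a synthetic phantom generator for
    aqueous mixtures and clot-like specimens with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
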