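Package: sfdose
Title: Small-Field Dosimetry Scan Metrics and Output-Factor Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for commissioning-grade analysis of small photon fields:
    reading and smoothing water-phantom scan curves, extracting depth-dose and
    profile metrics (PDD at depth, depth of maximum dose, FWHM, 20-80 percent
    penumbra), converting dosimetric field widths into the equivalent square
    field size, applying protocol-style field output correction factors
    including the intermediate field method daisy chain, and comparing
    detectors and commissioning datasets by percent standard deviation. A
    synthetic golden-beam and detector-response generator provides fully
    characterised test beams (erf-edged profiles with source-size blurring and
    small-field output drop, bi-exponential depth doses, micro-chamber volume
    averaging, shielded and unshielded diode response perturbations) so every
    stage of the pipeline can be validated without measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
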