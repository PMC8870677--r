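Package: radcomb
Title: Radiobiological Modelling of Combined Radium-223 and External Beam
    Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Linear-quadratic (LQ) radiobiology for treatments that combine the
    bone-seeking alpha-emitter radium-223 dichloride with external beam
    radiotherapy (EBRT) in metastatic castration-resistant prostate cancer.
    Implements biologically effective dose (BED) and 2 Gy equieffective dose
    (EQD2) for fractionated low-LET EBRT and for the continuously decaying
    high-LET mixture of Ra-223 and its decay-chain daughters (permanent-implant
    brachytherapy formalism with RBE_max weighting), constructs arm-level
    virtual cohorts from published trial summaries, and fits sample-size
    weighted logistic dose-response models for two-year overall survival and
    neutropenia, with fixed-effect and random-intercept (per study) variants.
    Includes a synthetic-data module for lesion-level dosimetry emulation and
    parameter-recovery simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    lme4,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
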