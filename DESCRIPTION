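Package: sclcgrowth
Title: Growth Kinetics of Peripheral Small-Cell Lung Cancer from Serial CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the natural growth history of peripheral
    small-cell lung cancer (and solid pulmonary nodules generally) from
    serial CT measurements. Implements dual-method volume-doubling-time
    (VDT) estimation -- a three-diameter calliper method and a
    segmentation-volume method via the modified Schwartz equation --
    together with growth-rate summaries, exponential and Gompertz
    growth-curve fitting with pattern classification, label-mask
    volumetry with isotropic resampling, cohort-level agreement and
    covariate statistics, and a reproducible synthetic serial-imaging
    cohort simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    RNifti
Config/testthat/edition: 3
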