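Package: atrquant
Title: Peak-Height-Ratio Quantification of Binary Drug Mixtures from ATR-FTIR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simultaneous quantification of two co-formulated active
    pharmaceutical ingredients (piperacillin and tazobactam) from attenuated
    total reflectance infrared spectra. Implements an anchored-baseline
    peak-height ratio statistic I(873)/I(890), a single least-squares
    calibration line against the closed-mixture transform x = 100/C_PIP,
    inverse prediction with first-order uncertainty propagation, and
    blank-based detection limits, together with a seeded pseudo-Voigt
    spectrum simulator for end-to-end validation and a manifest-driven
    calibrate/quantify/simulate pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'Spectrum-methods.R'
    'spectrum-io.R'
    'peak-heights.R'
    'peak-matching.R'
    'calibration.R'
    'detection-limits.R'
    'model-io.R'
    'reference-tables.R'
    'synthetic.R'
    'pipeline.R'
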