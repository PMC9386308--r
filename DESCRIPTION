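Package: grainspec
Title: NIRS Calibration Workflow for Grain Composition Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and validating near-infrared reflectance
    spectroscopy (NIRS) prediction models for grain composition traits
    (protein, total dietary fiber, starch, amylose, oil). Implements
    spectral-diversity-driven sample selection via Ward hierarchical
    clustering, scatter corrections (multiplicative scatter correction,
    standard normal variate with detrend), WinISI-style gap-derivative and
    moving-average math treatments, NIPALS partial least squares, modified
    PLS and principal component regression with block cross-validation and
    outlier elimination, and the external-validation statistics layer
    (RSQ, slope, bias, SEP, RPD, paired t-test). Includes a synthetic
    spectra generator that emulates a diverse brown-rice germplasm scan
    set so the full workflow can be exercised end-to-end without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
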