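Package: msiSO2
Title: Real-Time Skin Blood Oxygen Saturation Imaging from Snapshot
    Multispectral Data
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A Monte-Carlo-based framework for estimating microcirculatory
    blood oxygen saturation (SO2) in skin from snapshot multispectral images.
    A white Monte Carlo simulation of photon transport in a two-layer skin
    model feeds a four-dimensional reflectance look-up table; a forward
    camera model (sensor spectral response, optics, lamp, pixel
    amplification, detector noise) converts tissue reflectance into
    normalized 16-band spectra. SO2 is estimated either by iterative inverse
    Monte Carlo spectral fitting or by a small feed-forward neural network
    trained with Levenberg-Marquardt on synthetic spectra generated by the
    same forward model, at a small fraction of the inverse-fit cost. Includes
    sensor spectral-response calibration from tunable-filter sweeps, detector
    noise and lamp-variation model fitting, mosaic-sensor demosaicing and
    hypercube preprocessing, and synthetic phantom-scene generation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    minpack.lm,
    jsonlite,
    lhs
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllGenerics.R'
    'AllClasses.R'
    'spectra-core.R'
    'tissue-model.R'
    'mc-engine.R'
    'camera-model.R'
    'calibration.R'
    'synthgen.R'
    'estimators.R'
    'image-pipeline.R'
    'io.R'
    'msiSO2-package.R'
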