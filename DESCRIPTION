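Package: speckleRheo
Title: Stiffness Imaging from Dynamic Laser Speckle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Wide-field mapping of tissue stiffness surrogates from
    time series of laser speckle images. Implements pixel-wise diffuse
    correlation spectroscopy (g2 intensity autocorrelation and 1/e
    decorrelation-time extraction), a machine-learned decorrelation-time
    regressor trained on synthetic Brownian-motion speckle, and temporal
    laser speckle contrast imaging, together with a calibrated
    dynamic-speckle phantom simulator with ground-truth decorrelation-time
    maps, camera-noise models, region-of-interest statistics (mirrored
    control regions, SNR, Welch's t), and TIFF/JSON pipeline I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    signal,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'dcs.R'
    'io.R'
    'lsci.R'
    'mldcs.R'
    'phantom.R'
    'roi.R'
    'pipeline.R'
    'speckleRheo-package.R'
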