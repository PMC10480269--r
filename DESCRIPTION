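Package: respirolaser
Title: Simulated Laser-Spectroscopic Remote Sensing of Respiratory Rate
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward-models the reflection of a laser spot off a striped card
    mounted on an oscillating platform that mimics chest-wall displacement,
    renders the reflected power into time-resolved spectrometer frames with a
    configurable noise model, and recovers the oscillation frequency
    (respiratory rate) by slicing the intensity-time section at the laser
    line, smoothing, detrending and discrete Fourier analysis with sub-bin
    peak interpolation. Ships the 35-condition platform grid (7 motor speeds
    x 5 displacements), percent absolute-uncertainty scoring, and
    normal/abnormal rate classification with confusion metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'motion.R'
    'cardOptics.R'
    'acquisition.R'
    'spectraIO.R'
    'pipeline.R'
    'evaluation.R'
    'runConfig.R'
    'show-methods.R'
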