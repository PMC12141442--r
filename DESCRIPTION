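Package: swimetho
Title: Automated Seizure-Behavior Phenotyping from Larval Zebrafish Pose Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for quantifying larval zebrafish swim behavior in
    multi-well plates from eight-key-point pose tracks recorded at high frame
    rate. Implements a pixel-change activity metric with an inactivity
    exclusion rule, a track-cleaning cascade (implausible-speed gate,
    well-boundary gate, center-of-mass distance gate, sym4 wavelet denoising),
    per-frame swim kinematics (speed, distance, tail angle, heading-angle
    change, inter-eye distance), egocentrically aligned 60-frame feature
    windows, supervised five-class behavior classification (random forest,
    k-nearest-neighbour, support-vector), per-larva ethograms with
    behavior-fraction summaries, and a labelled synthetic swim simulator for
    end-to-end validation without recorded video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tiff,
    jsonlite,
    randomForest,
    e1071,
    class
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
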