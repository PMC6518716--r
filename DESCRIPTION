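Package: vesselmotion
Title: Multi-Camera Optical Measurement of Vessel Wall Deformation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Offline analysis chain for quantifying the wall motion of a
    pulsating elastic vessel phantom filmed by a ring of cameras. Provides a
    synthetic scene generator with exact ground truth (pulsating
    cross-section silhouettes and planar verification squares), a pinhole
    camera model with Brown-Conrady distortion including rectification and
    planar-target calibration, Otsu segmentation with largest-object area
    and caliper measurement, conversion of per-frame silhouette areas into
    shape deformation factors and millimetre wall displacement, a
    two-square accuracy-verification protocol, and Bland-Altman, Student t
    and Spearman statistics for agreement with reference measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    igraph,
    minpack.lm,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
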