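Package: cupball
Title: Markerless Tracking and Dynamics Analysis for Planar Cup-and-Ball
    Motor Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for camera-based assessment of upper-limb motor function
    with a tabletop cup-and-ball transport task. Provides planar homography
    registration of an overhead camera against a rectangular board,
    HSV-colour markerless tracking of a cup and a rolling ball, automatic
    detection of drawn circular targets and polygonal obstacles, a
    spherical-pendulum-on-cart model of the cup-and-ball dynamics with
    escape-angle geometry and safety margins, task outcome metrics (reach
    time, figure-eight tracking error, path variability), a verification
    pipeline (zero-phase Butterworth filtering, velocity-peak
    synchronization, Procrustes alignment, error and correlation measures),
    and a synthetic scene renderer that produces ground-truth-labelled
    frames and sessions so the whole pipeline can be exercised without
    hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    signal,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
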