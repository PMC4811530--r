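Package: vog3d
Title: Three-Dimensional Eye Rotation Vectors from High-Speed Video-Oculography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs three-dimensional rotation vectors of eye movements
    from two-dimensional video-oculography of the mouse eye. Provides geometric
    calibration of the center of eye rotation from pupil-ellipse minor axes,
    lifting of pupil-center and iris-freckle image coordinates onto their
    rotation spheres, rotation-vector and angular-velocity kinematics,
    turntable tracking from marker images, and vestibulo-ocular reflex (VOR)
    gain and phase estimation from sinusoid fits. A forward simulator generates
    ground-truth synthetic trajectories and rendered eye and turntable images
    so the whole pipeline can be validated without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    EBImage,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
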