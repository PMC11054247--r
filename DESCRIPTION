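Package: gait2d
Title: Markerless 2D Gait Analysis and Two-System Agreement Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for markerless sagittal-plane gait analysis from 2D pose
    keypoints: reading and cleaning per-frame keypoint series (OpenPose
    BODY_25 dialect), converting pixels to metric real-space coordinates
    through a Brown-Conrady lens model and pinhole geometry, detecting gait
    cycles by the ankle-under-hip crossing rule, computing spatiotemporal
    parameters (step length, stride length, stride time, gait speed) and
    sagittal hip/knee kinematics including the trailing limb angle, and the
    full method-comparison statistics battery used to validate one motion
    capture system against another: Shrout-Fleiss intraclass correlations
    with 95% confidence intervals, Cronbach's alpha, validity regression,
    and Bland-Altman analysis with fixed and proportional bias. Includes a
    ground-truthed synthetic kinematic walker for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
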