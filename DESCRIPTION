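Package: stackpose
Title: Full-Body Pose Estimation from Five Inertial Sensors with Stacked-Input Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates time-coherent full-body poses (23 body-segment
    orientation quaternions) from only five inertial sensors placed on the
    pelvis, both lower arms and both lower legs.  Implements pelvis-relative
    orientation and acceleration features, a stacked time-window input scheme
    with configurable past/future context, a shallow stacked-input neural
    network (SINN) and a bidirectional recurrent (bi-LSTM) baseline, forward
    kinematics over an anthropometric 23-segment skeleton, joint-position and
    jerk-based evaluation metrics under subject-wise cross-validation, a
    synthetic multi-subject motion generator, a plain-text motion interchange
    format, BVH import and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
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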