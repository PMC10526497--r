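Package: depthsim
Title: Binocular Depth Estimation by Hierarchical Active Inference
Version: 0.1.0
Authors@R:
    person("depthsim", "maintainers", email = "depthsim@example.org",
           role = c("aut", "cre"))
Description: Simulates an agent that estimates the depth of a 2D target from
    the projections seen by two eyes. The agent inverts a hierarchical
    generative model built from homogeneous-coordinate transforms (eye
    roto-translations and pinhole projections) using continuous-time
    predictive-coding message passing, and can actively verge its eyes on the
    target through alternating action and perception phases. Includes the
    generative process (world, eye kinematics, eccentricity-dependent fovea
    noise), a trial runner for the parallel-gaze, pre-verged, and active-vision
    model variants, metrics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
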