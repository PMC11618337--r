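Package: reachkin
Title: Reach-and-Place Wrist Kinematics, Group Statistics, and MLP Classification
Version: 0.1.0
Authors@R: person("Reach", "Kinematics Team", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing goal-directed reach-and-place movements
    recorded as 3-axis wrist displacement (e.g. from a wrist-worn inertial
    measurement unit sampled at 100 Hz). Provides a minimum-jerk synthetic
    trial generator with known ground truth, extraction of twelve kinematic
    parameters per trial (reaction time, movement time, total distance,
    velocity and acceleration summaries, and RMS movement-unit counts from
    zero-crossings of velocity, acceleration and jerk), nonparametric group
    comparisons with false-discovery-rate control, correlation tables against
    adaptive-functioning covariates, and a multilayer-perceptron classifier
    with ten-fold cross-validation and permutation feature importance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
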