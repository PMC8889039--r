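Package: anextrapush
Title: Simulation of Treadmill-Powered Ankle Push-Off Assistance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A planar torque-driven model of human treadmill walking coupled to
    AN-EXTRA-Push, an ankle exoskeleton that harnesses energy of the moving
    treadmill belt in an elastic tendon via a brake and a three-spool
    transmission and returns it as plantarflexion assistance during push-off.
    Provides the ten-segment multibody gait model with penalty foot-ground
    contact and belt friction, PID tracking control driven by synthetic
    periodic reference kinematics, the brake/elastic-tendon exoskeleton model,
    genetic-algorithm adjustment of reference kinematics, and the
    parameter-sweep machinery for push-off work metrics (positive ankle work
    reduction, disengagement-timing groups, sweep regressions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
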