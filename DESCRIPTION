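Package: rheodipole
Title: Finite-Dipole Modeling and Calibration of Zebrafish Rheotaxis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and calibrates a finite-dipole model of adult
    zebrafish swimming in a uniaxial channel flow. The swimmer is a pair
    of point vortices whose strengths evolve as coupled Cox-Ingersoll-Ross
    stochastic processes under multi-sensory feedback: hydromechanical
    sensing of the local flow circulation through the lateral line, visual
    wall avoidance, and tactile collision responses. Provides in-silico
    rheotaxis experiments at 30 Hz in a rectangular test section, inverse
    kinematics to recover vortex strengths from tracked trajectories,
    maximum-likelihood calibration of the stochastic model with a Feller
    positivity constraint, Markov-rate estimation of the sensory switching
    process, a four-step wall-parameter calibration, and behavioral scoring
    (rheotaxis index, heading cosine, spatial entropy).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
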