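Package: dyadmimicry
Title: Minimal Agent-Based Model of Mimicry Through Perceptual Crossing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates two embodied agents, each a continuous-time recurrent
    neural network (CTRNN) controller rigidly linked to a body-object and a
    receptor field in a shared one-dimensional space, who interact through
    all-or-nothing tactile perceptual crossing and converge on matching
    ("mimicking") body configurations without ever sensing their own or the
    other's configuration. Provides the coupled trial simulator (Euler
    integration with a compiled core), a genetic algorithm over clonal
    controller parameters and embodiment gains, numerical fixed-point and
    attractor analysis of the evolved controllers, and analysis metrics for
    body-offset convergence, link-distance diversity growth, role division,
    button-use strategies, interaction correlations and movement synchrony.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
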