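Package: coordlearn
Title: Simulation and Analysis of Coordinated Rhythmic Movement Learning
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studies of bimanual coordinated rhythmic movement
    learning. Provides a coupled-oscillator generator for synthetic
    two-channel movement trials and simulated two-alternative forced-choice
    observers; a kinematic pipeline that turns raw joystick position traces
    into continuous relative phase and proportion-of-time-on-target scores;
    the feedback-fading training protocol (coordination feedback,
    knowledge-of-results, bandwidth progression and stop rules); transformed
    1-up/2-down adaptive staircases with position-perturbed displays and
    reversal-based threshold estimation; and the statistical layer
    (lambda-weighted dependent-measures contrasts with Hedges' g,
    Holm-Bonferroni correction, proportion-of-transfer, and exponential
    learning-curve fits with derivative-based learning rates).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
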