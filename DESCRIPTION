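Package: predcoding
Title: Predictive Coding and Backpropagation for Feedforward Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements supervised learning by predictive coding for arbitrary
    layered feedforward networks: a strict free-energy formulation whose belief
    dynamics descend the total prediction-error objective, the fixed-prediction
    variant whose converged parameter updates equal backpropagation gradients,
    and precision-weighted prediction errors.  Provides a backpropagation
    reference built on per-layer vector-Jacobian adjoints, a central
    finite-difference gradient oracle, fixed-point diagnostics, comparison
    metrics between update rules, a seeded mini-batch training loop with SGD
    and Adam, synthetic dataset generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
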