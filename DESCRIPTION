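Package: gradientforge
Title: Inverse Design of Electrochemically Generated Oxygen and Hydrogen
    Peroxide Microgradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the steady-state oxygen and hydrogen peroxide
    concentration gradients generated by microwire-array electrodes
    driving the oxygen reduction reaction, and inverts the model to find
    electrode morphologies producing a user-specified gradient. Includes
    a finite-volume reaction-diffusion solver with concentration-dependent
    Tafel boundary kinetics on a periodic unit cell, batch generation of
    simulated gradient datasets, a multilayer-perceptron surrogate that
    emulates the solver, and a similarity-score search over the morphology
    space with sliced score maps and full-simulation verification of
    candidate designs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
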