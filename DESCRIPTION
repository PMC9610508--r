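Package: mitnet
Title: Magnetic Induction Tomography Simulation and Deep Residual Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Physics-based forward simulation and learned inverse reconstruction
    for 3D magnetic induction tomography (MIT) of torso-sized conductive bodies.
    Provides analytic Biot-Savart vector potentials for an undulator exciter and
    butterfly gradiometric receivers, a resistor-network nodal-analysis solver
    for the induced scalar potential and eddy currents, Geselowitz-reciprocity
    receiver projection, a synthetic dataset generator with inverse-crime
    avoidance (fine simulation grid versus coarse reconstruction grid, additive
    measurement noise, differential signalling), a self-contained residual 2D
    convolutional network with two-phase Huber-loss training, and the full
    evaluation metric suite (MSE, MAE, Pearson correlation, SSIM).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
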