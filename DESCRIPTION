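Package: warpmix
Title: Hierarchical Time Warping and Factor Analysis of Movement Curves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simultaneous separation of timing and amplitude variation in
    repeated functional observations such as movement signals. Implements a
    hierarchical nonlinear mixed-effects model in which a common B-spline
    template and participant-specific deviations are composed with piecewise
    linear time warps (participant-level fixed anchors plus repetition-level
    Gaussian anchors with a Brownian-bridge covariance), serially correlated
    Matern amplitude variation and white observation noise. Parameters are
    estimated by an alternating three-level maximum-likelihood scheme with a
    Laplace-type linearized marginal likelihood for the variance components.
    Includes posterior-distance classification of repetitions to participants
    with chronological cross-validation, a companion mixed-effects factor
    model for temporally aligned three-dimensional movement paths fitted by
    an ECM algorithm with SQUAREM acceleration (orthonormal loadings, three
    nested Gaussian random-effect levels, covariate design in obstacle
    height, likelihood-ratio design comparison, prediction ellipsoids), and
    synthetic-data generators for both models.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    splines,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
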