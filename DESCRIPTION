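Package: wiresbi
Title: Simulation-Based Inference for Generative Connectome Wiring Rules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for formulating axo-dendritic wiring rules as stochastic
    simulators over a voxelized structural model of neural tissue and for
    inferring their parameters from measured population connection
    probabilities with simulation-based inference. Provides a synthetic
    structural-model generator (sparse per-neuron bouton and postsynaptic
    target counts over a 3D subvolume grid), three parametrized wiring-rule
    simulators (a dense-structural-overlap rule with Poisson synapse counts
    and its Poisson-GLM form, a neuron-level shared-subvolume threshold rule,
    and a synapse-level Bernoulli rule, including Peters'-rule special
    cases), population connection-probability summary statistics, neural
    posterior estimation with a mixture-density conditional estimator and a
    truncated sequential variant, a reduced simulator with analytic Poisson
    likelihood and a slice-sampling MCMC reference posterior, and a
    validation suite covering simulation-based calibration, classifier
    two-sample tests, predictive checks, posterior correlation structure,
    conditional correlations, and leave-one-measurement-out prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    nnet,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
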