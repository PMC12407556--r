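Package: coopnet
Title: Cooperative Coding in Sparse Recurrent Neural Networks
Version: 0.1.0
Description: Simulation and analysis of cooperatively coding neural networks,
    in which broad, exponentially decaying receptive fields are constructed
    from minimal recurrent connectivity instead of dense feedforward wiring.
    Provides linear rate-network models on rings, mixed-selectivity grids and
    tori, exact synapse accounting for feedforward versus cooperative
    architectures, response-time measurement and spectral theory, response
    acceleration through spike-frequency adaptation and through delayed
    balancing inhibition (delay differential dynamics and dominant-root
    analysis), and leaky integrate-and-fire spiking implementations with
    diffusion-approximation weight tuning. Includes fast compiled integrators,
    scaling experiments with power-law fits, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
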