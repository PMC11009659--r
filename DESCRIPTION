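Package: vesikit
Title: Kinetic Modelling and Estimation of Synaptic Vesicle Priming and Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing transmitter release at
    chemical synapses with a sequential two-step vesicle priming scheme
    (loosely and tightly docked states) extended by a faulty-primed vesicle
    state. Provides a mean-field (ODE) simulator and an exact stochastic
    simulator of the scheme driven by an effective intracellular calcium
    transient, nonnegative tensor factorization of quantal release trains
    into per-synapse amplitudes and shared basefunctions, fusion-probability
    and per-interval priming estimators, cumulative back-extrapolation pool
    estimators with interstimulus-interval correction, derivative-threshold
    quantal event detection on postsynaptic current traces, and a synthetic
    data generator producing release tensors and noisy current traces with
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
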