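# shared fixtures: parameter sets built in code

# a parameter set with every transition frozen except AP-triggered fusion:
# the train response is an exact geometric series
frozenParams <- function(p = 0.48, nTot = 1900) {
  modelParams(
    nTot = nTot,
    priming1 = primingLaw(0, 0, 100), b1 = 0,
    priming2 = primingLaw(0, 0, 100), b2 = 0,
    sk = 0, bf = 0, kfMax = 0,
    pFusion = p, sAp = 0, kUntight = 0,
    tsLaw = fusionLaw(0, 1e-12, 1, 1e9),   # effectively zero fusion rate
    fsLaw = fusionLaw(0, 1e-12, 1, 1e9),
    ca = calciumParams(), label = "frozen")
}

# a small, fast generic parameter set for property tests (not calibrated)
toyParams <- function() {
  modelParams(
    nTot = 500,
    priming1 = primingLaw(0.5, 2, 300), b1 = 0.1,
    priming2 = primingLaw(0.05, 0.3, 10), b2 = 0.05,
    sk = 0.05, bf = 1, kfMax = 1,
    pFusion = 0.3, sAp = 0.08, kUntight = 5,
    tsLaw = fusionLaw(0.01, 2e4, 4, 3e4),
    fsLaw = fusionLaw(0, 2.72, 3.4, 107),
    ca = calciumParams(50, 110, 25, 0.04, 0.3), label = "toy")
}

# collapsed model: sites fuse from TS at a constant rate and are recycled
# back almost instantly, so the ensemble event train is Poisson
poissonParams <- function(rate, nTot = 30) {
  modelParams(
    nTot = nTot,
    priming1 = primingLaw(5e4, 5e4, 100), b1 = 0,
    priming2 = primingLaw(5e4, 5e4, 100), b2 = 0,
    sk = 0, bf = 0, kfMax = 0,
    pFusion = 0, sAp = 0, kUntight = 0,
    tsLaw = fusionLaw(rate, rate * (1 + 1e-9), 1, 1e9),
    fsLaw = fusionLaw(0, 1e-12, 1, 1e9),
    ca = calciumParams(), label = "poisson")
}
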