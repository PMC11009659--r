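#' @import methods
NULL

.STATES <- c("es", "ls", "ts", "tsl", "fs")

#' Effective presynaptic calcium transient parameters
#'
#' Global (spatially averaged) free calcium is modelled as a resting level
#' plus one instantaneous increment per action potential that decays with a
#' double-exponential timecourse. This "effective" calcium drives the
#' calcium-dependent acceleration of vesicle priming and the asynchronous
#' fusion rate laws; local microdomain calcium at the release site is not
#' modelled.
#'
#' @slot cRest resting concentration (nM)
#' @slot aFast,aSlow per-AP increment amplitudes of the fast and slow
#'   components (nM)
#' @slot tauFast,tauSlow decay time constants (s)
#' @export
setClass("CalciumParams",
  representation(cRest = "numeric", aFast = "numeric", aSlow = "numeric",
                 tauFast = "numeric", tauSlow = "numeric"),
  prototype(cRest = 50, aFast = 120, aSlow = 25, tauFast = 0.04,
            tauSlow = 0.35))

setValidity("CalciumParams", function(object) {
  v <- c(object@cRest, object@aFast, object@aSlow, object@tauFast,
         object@tauSlow)
  if (any(!is.finite(v)) || any(v <= 0))
    return("all calcium parameters must be finite and > 0")
  if (object@aFast + object@aSlow >= 200)
    return("single-AP peak increment aFast + aSlow must stay below 200 nM")
  TRUE
})

#' Hill-type calcium dependence of the vesicle fusion rate
#'
#' rate(c) = basal + (gammaMax - basal) * c^n / (c^n + kd^n). Used both for
#' the steeply calcium-dependent fusion of tightly docked vesicles and for
#' the shallow, high-affinity fusion law of faulty-primed vesicles.
#'
#' @slot basal rate at zero calcium (1/s)
#' @slot gammaMax saturating rate (1/s)
#' @slot hillN Hill coefficient (dimensionless)
#' @slot kd apparent dissociation constant (nM)
#' @export
setClass("FusionLaw",
  representation(basal = "numeric", gammaMax = "numeric", hillN = "numeric",
                 kd = "numeric"),
  prototype(basal = 0, gammaMax = 2.72, hillN = 3.4, kd = 107))

setValidity("FusionLaw", function(object) {
  if (object@basal < 0) return("basal must be >= 0")
  if (object@gammaMax <= object@basal) return("gammaMax must exceed basal")
  if (object@hillN <= 0) return("hillN must be > 0")
  if (object@kd <= 0) return("kd must be > 0")
  TRUE
})

#' Saturating calcium dependence of a forward priming rate constant
#'
#' rate(c) = kRest + (kMax - kRest) * d / (d + kHalf) with d = max(c - c0, 0).
#' The rate equals kRest at resting calcium and rises monotonically to kMax;
#' kHalf sets the calcium increment above rest producing half-maximal
#' acceleration.
#'
#' @slot kRest resting rate (1/s)
#' @slot kMax saturated rate (1/s)
#' @slot kHalf half-activation increment above rest (nM)
#' @slot c0 activation offset, normally the resting calcium (nM)
#' @export
setClass("PrimingLaw",
  representation(kRest = "numeric", kMax = "numeric", kHalf = "numeric",
                 c0 = "numeric"),
  prototype(kRest = 0.5, kMax = 0.5, kHalf = 100, c0 = 50))

setValidity("PrimingLaw", function(object) {
  if (object@kRest < 0 || object@kMax < object@kRest)
    return("need 0 <= kRest <= kMax")
  if (object@kHalf <= 0) return("kHalf must be > 0")
  TRUE
})

#' Full parameter set of the extended priming/fusion scheme
#'
#' States: ES (empty site), LS (loosely docked), TS (tightly docked,
#' fusion-competent), TSL (labile tightly docked, generated from LS by an
#' AP), FS (faulty-primed). Forward priming rates k1 (ES->LS), k2 (LS->TS)
#' and kf (ES->FS) are calcium dependent; backward rates b1, b2, bf are not.
#' kf at rest is tied to k1 by the scaling factor sk (kf = sk * k1 at every
#' calcium level). An AP fuses TS/TSL vesicles with probability pFusion and
#' converts the fraction sAp of LS to TSL; TSL relaxes back to LS at
#' kUntight. Fused vesicles free their sites (return to ES).
#'
#' @slot nTot total number of vesicle docking sites
#' @slot priming1,priming2 calcium-dependent laws of k1 and k2
#' @slot b1,b2 backward rates LS->ES and TS->LS (1/s)
#' @slot sk dimensionless scaling kf = sk * k1
#' @slot primingF calcium-dependent law of kf (derived: sk-scaled priming1)
#' @slot bf backward rate FS->ES (1/s)
#' @slot pFusion per-AP fusion probability of TS/TSL vesicles
#' @slot sAp per-AP LS->TSL conversion fraction
#' @slot kUntight TSL->LS relaxation rate (1/s)
#' @slot tsLaw,fsLaw fusion rate laws for TS/TSL and FS vesicles
#' @slot ca effective calcium transient parameters
#' @slot label free-text genotype/condition label
#' @export
setClass("ModelParams",
  representation(nTot = "numeric", priming1 = "PrimingLaw", b1 = "numeric",
                 priming2 = "PrimingLaw", b2 = "numeric", sk = "numeric",
                 primingF = "PrimingLaw", bf = "numeric", pFusion = "numeric",
                 sAp = "numeric", kUntight = "numeric", tsLaw = "FusionLaw",
                 fsLaw = "FusionLaw", ca = "CalciumParams",
                 label = "character"),
  prototype(nTot = 1900, b1 = 0.06, b2 = 0.02, sk = 0.0065, bf = 2,
            pFusion = 0.48, sAp = 0.05, kUntight = 30, label = ""))

setValidity("ModelParams", function(object) {
  if (object@nTot <= 0) return("nTot must be > 0")
  if (object@pFusion < 0 || object@pFusion > 1)
    return("pFusion must lie in [0, 1]")
  if (object@sAp < 0 || object@sAp > 1) return("sAp must lie in [0, 1]")
  if (object@b1 < 0 || object@b2 < 0 || object@bf < 0 || object@kUntight < 0)
    return("backward rates must be >= 0")
  if (object@sk < 0) return("sk must be >= 0")
  if (abs(object@primingF@kRest - object@sk * object@priming1@kRest) >
      1e-9 * max(1, object@priming1@kRest))
    return("primingF must be the sk-scaled copy of priming1")
  TRUE
})

#' Stimulus protocol: ordered AP times within a simulation window
#'
#' @slot apTimes strictly increasing AP times (s); may be empty
#' @slot duration total simulated time (s)
#' @export
setClass("StimulusProtocol",
  representation(apTimes = "numeric", duration = "numeric"),
  prototype(apTimes = numeric(0), duration = 1))

setValidity("StimulusProtocol", function(object) {
  if (length(object@duration) != 1 || object@duration <= 0)
    return("duration must be a single positive number")
  if (length(object@apTimes)) {
    if (any(diff(object@apTimes) <= 0))
      return("apTimes must be strictly increasing")
    if (min(object@apTimes) < 0 || max(object@apTimes) > object@duration)
      return("apTimes must lie within [0, duration]")
  }
  TRUE
})

#' Mean-field trajectory of the kinetic scheme
#'
#' @slot times output grid (s)
#' @slot states matrix of occupancies, columns es/ls/ts/tsl/fs (values at AP
#'   times are the pre-jump states)
#' @slot ca effective calcium on the grid (nM)
#' @slot xi asynchronous release rate on the grid (quanta/s)
#' @slot m quantal content per AP (synchronous release)
#' @slot apTimes AP times of the simulated protocol (s)
#' @export
setClass("Trajectory",
  representation(times = "numeric", states = "matrix", ca = "numeric",
                 xi = "numeric", m = "numeric", apTimes = "numeric"))

setValidity("Trajectory", function(object) {
  if (!identical(colnames(object@states), .STATES))
    return("states must have columns es, ls, ts, tsl, fs")
  if (nrow(object@states) != length(object@times))
    return("states and times disagree in length")
  if (any(object@xi < -1e-9)) return("xi must be nonnegative")
  TRUE
})

#' Timestamped asynchronous quantal release events from a stochastic run
#'
#' Holds the rate-driven (spontaneous/delayed) fusion events; AP-evoked
#' synchronous fusion counts are kept separately per stimulus in mEvoked,
#' mirroring the blanking of evoked responses during event analysis.
#'
#' @slot times strictly increasing event times (s)
#' @slot origin state of the fusing vesicle per event ("TS", "TSL" or "FS")
#' @slot seed RNG seed of the run
#' @slot nSites number of simulated docking sites
#' @slot duration simulated time (s)
#' @slot mEvoked AP-evoked fused counts, one per AP
#' @slot apTimes AP times (s)
#' @export
setClass("EventTrain",
  representation(times = "numeric", origin = "character", seed = "numeric",
                 nSites = "numeric", duration = "numeric",
                 mEvoked = "numeric", apTimes = "numeric"),
  prototype(mEvoked = numeric(0), apTimes = numeric(0)))

setValidity("EventTrain", function(object) {
  if (length(object@times) != length(object@origin))
    return("times and origin disagree in length")
  if (length(object@times) && any(diff(object@times) <= 0))
    return("event times must be strictly increasing")
  if (length(object@origin) &&
      !all(object@origin %in% c("TS", "TSL", "FS")))
    return("origin labels must be TS, TSL or FS")
  TRUE
})

#' Quantal release train tensor m[synapse, frequency, stimulus]
#'
#' @slot m 3-d array of quantal contents
#' @slot mask logical array, TRUE where an entry is present
#' @slot freqs stimulation frequencies (Hz), one per slice of dim 2
#' @slot nAps number of APs per frequency
#' @slot synapseIds identifiers, one per slice of dim 1
#' @export
setClass("ReleaseTensor",
  representation(m = "array", mask = "array", freqs = "numeric",
                 nAps = "numeric", synapseIds = "character"))

setValidity("ReleaseTensor", function(object) {
  d <- dim(object@m)
  if (length(d) != 3) return("m must be a 3-d array")
  if (!identical(dim(object@mask), d)) return("mask must match dim(m)")
  if (length(object@freqs) != d[2]) return("freqs must match dim 2")
  if (length(object@nAps) != d[2]) return("nAps must match dim 2")
  if (length(object@synapseIds) != d[1])
    return("synapseIds must match dim 1")
  if (any(object@m[object@mask] < 0, na.rm = TRUE))
    return("quantal contents must be >= 0 where mask is TRUE")
  TRUE
})

#' Result of a nonnegative tensor factorization of a release tensor
#'
#' Reconstruction: m[i, f, j] ~ sum_c amplitudes[i, c] *
#' basefunctions[c, f, j]. Depleting components (component 1, and component
#' 2 in a three-component fit) have per-frequency unit-sum basefunctions so
#' that their amplitudes are quanta contributed by the corresponding
#' preexisting pool.
#'
#' @slot amplitudes matrix synapse x component
#' @slot basefunctions array component x frequency x stimulus
#' @slot sse masked sum of squared residuals at convergence
#' @slot nIter iterations used
#' @slot converged logical
#' @slot freqs frequencies (Hz) of dim 2
#' @export
setClass("NtfResult",
  representation(amplitudes = "matrix", basefunctions = "array",
                 sse = "numeric", nIter = "numeric", converged = "logical",
                 freqs = "numeric"))

#' Uniformly sampled postsynaptic current trace
#'
#' @slot samples current (pA); EPSCs are negative-going deflections
#' @slot dt sampling interval (s)
#' @slot t0 time of the first sample (s)
#' @slot trueEventTimes ground-truth event times if synthetic (s)
#' @slot trueAmps ground-truth event amplitudes (pA)
#' @export
setClass("CurrentTrace",
  representation(samples = "numeric", dt = "numeric", t0 = "numeric",
                 trueEventTimes = "numeric", trueAmps = "numeric"),
  prototype(t0 = 0, trueEventTimes = numeric(0), trueAmps = numeric(0)))

setValidity("CurrentTrace", function(object) {
  if (object@dt <= 0) return("dt must be > 0")
  if (any(!is.finite(object@samples))) return("samples must be finite")
  TRUE
})

#' Binned quantal release rate timecourse xi(t)
#'
#' @slot binEdges bin edges (s), length nBins + 1
#' @slot rate quanta/s per bin
#' @export
setClass("RateTimecourse",
  representation(binEdges = "numeric", rate = "numeric"))

setValidity("RateTimecourse", function(object) {
  if (length(object@binEdges) != length(object@rate) + 1)
    return("binEdges must have length(rate) + 1")
  if (any(object@rate < 0)) return("rates must be >= 0")
  TRUE
})

#' Specification of a synthetic synapse population
#'
#' @slot nSynapses number of synapses
#' @slot mtsRange (low, high) of the log-uniform resting TS pool draw
#' @slot quantalNoiseCv multiplicative noise CV applied to each quantal
#'   content
#' @slot freqs train frequencies (Hz)
#' @slot nAps APs per train
#' @slot seed integer RNG seed
#' @export
setClass("PopulationSpec",
  representation(nSynapses = "numeric", mtsRange = "numeric",
                 quantalNoiseCv = "numeric", freqs = "numeric",
                 nAps = "numeric", seed = "numeric"),
  prototype(nSynapses = 14, mtsRange = c(110, 1571), quantalNoiseCv = 0.05,
            freqs = c(5, 10, 20, 50, 100, 200), nAps = 40, seed = 1))

setValidity("PopulationSpec", function(object) {
  if (object@nSynapses < 2) return("need at least 2 synapses")
  if (length(object@mtsRange) != 2 ||
      object@mtsRange[1] >= object@mtsRange[2] || object@mtsRange[1] <= 0)
    return("mtsRange must be (low, high) with 0 < low < high")
  if (object@quantalNoiseCv < 0) return("quantalNoiseCv must be >= 0")
  TRUE
})

#' Quantal waveform used to render events into a current trace
#'
#' Single quantum: difference of exponentials with unit peak, scaled by a
#' beta-distributed amplitude (skewed, as observed for miniature event
#' amplitude distributions).
#'
#' @slot riseTau,decayTau rise/decay time constants (s)
#' @slot meanAmp mean event amplitude (pA)
#' @slot ampBetaA,ampBetaB beta shape parameters of the amplitude draw
#' @slot ampMax amplitude scale: amp = ampMax * Beta(a, b) (pA)
#' @export
setClass("QuantalWaveform",
  representation(riseTau = "numeric", decayTau = "numeric",
                 meanAmp = "numeric", ampBetaA = "numeric",
                 ampBetaB = "numeric", ampMax = "numeric"),
  prototype(riseTau = 2e-4, decayTau = 1e-3, meanAmp = 30, ampBetaA = 2,
            ampBetaB = 4, ampMax = 90))

setValidity("QuantalWaveform", function(object) {
  if (object@riseTau >= object@decayTau)
    return("riseTau must be smaller than decayTau")
  if (object@meanAmp <= 0) return("meanAmp must be > 0")
  if (object@ampBetaA <= 0 || object@ampBetaB <= 0 || object@ampMax <= 0)
    return("beta amplitude parameters must be > 0")
  TRUE
})
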