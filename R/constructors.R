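#' Construct calcium transient parameters
#'
#' @param cRest resting free calcium (nM)
#' @param aFast,aSlow per-AP increments (nM)
#' @param tauFast,tauSlow decay time constants (s)
#' @return a [CalciumParams-class] object
#' @export
calciumParams <- function(cRest = 50, aFast = 120, aSlow = 25,
                          tauFast = 0.04, tauSlow = 0.35) {
  new("CalciumParams", cRest = cRest, aFast = aFast, aSlow = aSlow,
      tauFast = tauFast, tauSlow = tauSlow)
}

#' Construct a Hill-type fusion rate law
#'
#' @param basal rate at zero calcium (1/s)
#' @param gammaMax saturating rate (1/s)
#' @param hillN Hill coefficient
#' @param kd apparent KD (nM)
#' @return a [FusionLaw-class] object
#' @export
fusionLaw <- function(basal = 0, gammaMax = 2.72, hillN = 3.4, kd = 107) {
  new("FusionLaw", basal = basal, gammaMax = gammaMax, hillN = hillN,
      kd = kd)
}

#' Construct a saturating priming rate law
#'
#' @param kRest resting rate (1/s)
#' @param kMax saturated rate (1/s)
#' @param kHalf half-activation calcium increment above rest (nM)
#' @param c0 activation offset (nM), normally the resting calcium
#' @return a [PrimingLaw-class] object
#' @export
primingLaw <- function(kRest, kMax = kRest, kHalf = 100, c0 = 50) {
  new("PrimingLaw", kRest = kRest, kMax = kMax, kHalf = kHalf, c0 = c0)
}

.scaleLaw <- function(law, s) {
  new("PrimingLaw", kRest = s * law@kRest, kMax = s * law@kMax,
      kHalf = law@kHalf, c0 = law@c0)
}

#' Construct a full model parameter set
#'
#' The resting ES->FS rate is tied to the first priming step by the
#' checkpoint-leakiness scaling `sk` (kf_rest = sk * k1_rest); the
#' calcium-accelerated ceiling `kfMax` of the faulty branch is its own
#' (calibrated) parameter, with the same half-activation as k1 unless
#' overridden.
#'
#' @param nTot number of docking sites
#' @param priming1,priming2 [PrimingLaw-class] objects for k1 and k2
#' @param b1,b2,bf backward rates (1/s)
#' @param sk kf_rest/k1_rest scaling factor
#' @param kfMax saturated ES->FS rate (1/s); defaults to sk * k1 kMax
#' @param kfHalf half-activation of the ES->FS acceleration (nM); defaults
#'   to the k1 value
#' @param pFusion per-AP fusion probability of TS/TSL vesicles
#' @param sAp per-AP LS->TSL conversion fraction
#' @param kUntight TSL->LS rate (1/s)
#' @param tsLaw,fsLaw [FusionLaw-class] objects
#' @param ca [CalciumParams-class] object
#' @param label free-text label
#' @return a [ModelParams-class] object
#' @export
modelParams <- function(nTot = 1900, priming1, b1, priming2, b2, sk, bf,
                        pFusion, sAp, kUntight = 30, tsLaw, fsLaw,
                        ca = calciumParams(), kfMax = NULL, kfHalf = NULL,
                        label = "") {
  if (is.null(kfMax)) kfMax <- sk * priming1@kMax
  if (is.null(kfHalf)) kfHalf <- priming1@kHalf
  pF <- primingLaw(sk * priming1@kRest, max(kfMax, sk * priming1@kRest),
                   kfHalf, c0 = priming1@c0)
  new("ModelParams", nTot = nTot, priming1 = priming1, b1 = b1,
      priming2 = priming2, b2 = b2, sk = sk,
      primingF = pF, bf = bf, pFusion = pFusion,
      sAp = sAp, kUntight = kUntight, tsLaw = tsLaw, fsLaw = fsLaw,
      ca = ca, label = label)
}

#' Replace the kf_rest/k1_rest scaling factor of a parameter set
#'
#' The whole faulty-branch law scales proportionally (leakier checkpoint:
#' faster ES->FS transition at every calcium level).
#'
#' @param params a [ModelParams-class] object
#' @param sk new scaling factor
#' @return the modified parameter set
#' @export
setSk <- function(params, sk) {
  fac <- if (params@sk > 0) sk / params@sk else NA
  old <- params@primingF
  params@primingF <- if (is.finite(fac))
    primingLaw(fac * old@kRest, fac * old@kMax, old@kHalf, old@c0)
  else
    primingLaw(sk * params@priming1@kRest, sk * params@priming1@kMax,
               old@kHalf, old@c0)
  params@sk <- sk
  validObject(params)
  params
}

#' Construct a stimulus protocol from explicit AP times
#'
#' @param apTimes strictly increasing AP times (s)
#' @param duration simulated time (s); defaults to 0.5 s past the last AP
#' @return a [StimulusProtocol-class] object
#' @export
stimulusProtocol <- function(apTimes, duration = NULL) {
  if (is.null(duration))
    duration <- if (length(apTimes)) max(apTimes) + 0.5 else 1
  new("StimulusProtocol", apTimes = as.numeric(apTimes),
      duration = duration)
}

#' Construct a regular train protocol
#'
#' @param freqHz stimulation frequency (Hz)
#' @param nAps number of APs
#' @param start time of the first AP (s)
#' @param tail simulated time after the last AP (s)
#' @return a [StimulusProtocol-class] object
#' @export
trainProtocol <- function(freqHz, nAps, start = 0, tail = 0.5) {
  times <- start + (seq_len(nAps) - 1) / freqHz
  stimulusProtocol(times, duration = max(times) + tail)
}

#' Construct a synthetic population specification
#'
#' Defaults mirror the recorded wild-type ensemble: 14 synapses, resting TS
#' pools spanning 110 to 1571 vesicles, 5-200 Hz trains of 40 APs.
#'
#' @param nSynapses number of synapses
#' @param mtsRange (low, high) of the log-uniform resting TS pool draw
#' @param quantalNoiseCv multiplicative noise CV per quantal content
#' @param freqs train frequencies (Hz)
#' @param nAps APs per train
#' @param seed integer RNG seed
#' @return a [PopulationSpec-class] object
#' @export
populationSpec <- function(nSynapses = 14, mtsRange = c(110, 1571),
                           quantalNoiseCv = 0.05,
                           freqs = c(5, 10, 20, 50, 100, 200), nAps = 40,
                           seed = 1) {
  new("PopulationSpec", nSynapses = nSynapses, mtsRange = mtsRange,
      quantalNoiseCv = quantalNoiseCv, freqs = freqs, nAps = nAps,
      seed = seed)
}

#' Construct a quantal waveform
#'
#' @param riseTau,decayTau rise/decay time constants (s)
#' @param meanAmp mean amplitude (pA)
#' @param ampBetaA,ampBetaB beta shape parameters
#' @param ampMax amplitude scale (pA); defaults so the beta mean equals
#'   `meanAmp`
#' @return a [QuantalWaveform-class] object
#' @export
quantalWaveform <- function(riseTau = 2e-4, decayTau = 1e-3, meanAmp = 30,
                            ampBetaA = 2, ampBetaB = 4, ampMax = NULL) {
  if (is.null(ampMax))
    ampMax <- meanAmp * (ampBetaA + ampBetaB) / ampBetaA
  new("QuantalWaveform", riseTau = riseTau, decayTau = decayTau,
      meanAmp = meanAmp, ampBetaA = ampBetaA, ampBetaB = ampBetaB,
      ampMax = ampMax)
}

#' Construct a release tensor
#'
#' @param m 3-d array `[synapse, frequency, stimulus]` of quantal contents
#' @param freqs frequencies (Hz)
#' @param mask logical presence array; defaults to non-NA entries of m
#' @param nAps APs per frequency; defaults to dim 3
#' @param synapseIds synapse identifiers
#' @return a [ReleaseTensor-class] object
#' @export
releaseTensor <- function(m, freqs, mask = NULL, nAps = NULL,
                          synapseIds = NULL) {
  if (is.null(mask)) mask <- !is.na(m)
  if (is.null(nAps)) nAps <- rep(dim(m)[3], dim(m)[2])
  if (is.null(synapseIds)) synapseIds <- paste0("syn", seq_len(dim(m)[1]))
  m[!mask] <- 0
  new("ReleaseTensor", m = m, mask = mask, freqs = freqs, nAps = nAps,
      synapseIds = synapseIds)
}

#' Construct a current trace
#'
#' @param samples current samples (pA)
#' @param dt sampling interval (s)
#' @param t0 time of first sample (s)
#' @param trueEventTimes,trueAmps optional ground-truth annotations
#' @return a [CurrentTrace-class] object
#' @export
currentTrace <- function(samples, dt, t0 = 0,
                         trueEventTimes = numeric(0),
                         trueAmps = numeric(0)) {
  new("CurrentTrace", samples = samples, dt = dt, t0 = t0,
      trueEventTimes = trueEventTimes, trueAmps = trueAmps)
}

#' @export
setMethod("show", "ModelParams", function(object) {
  cat("ModelParams", if (nzchar(object@label)) sprintf("[%s]", object@label),
      "\n")
  cat(sprintf("  nTot = %g sites, pFusion = %.3g, sAp = %.3g\n",
              object@nTot, object@pFusion, object@sAp))
  cat(sprintf("  k1: %.3g -> %.3g 1/s (kHalf %.3g nM); b1 = %.3g\n",
              object@priming1@kRest, object@priming1@kMax,
              object@priming1@kHalf, object@b1))
  cat(sprintf("  k2: %.3g -> %.3g 1/s (kHalf %.3g nM); b2 = %.3g\n",
              object@priming2@kRest, object@priming2@kMax,
              object@priming2@kHalf, object@b2))
  cat(sprintf("  kf = %.3g * k1, bf = %.3g, kUntight = %.3g\n",
              object@sk, object@bf, object@kUntight))
  cat(sprintf("  TS law: basal %.3g, gamma %.3g (n %.3g, KD %.3g nM)\n",
              object@tsLaw@basal, object@tsLaw@gammaMax, object@tsLaw@hillN,
              object@tsLaw@kd))
  cat(sprintf("  FS law: basal %.3g, gamma %.3g (n %.3g, KD %.3g nM)\n",
              object@fsLaw@basal, object@fsLaw@gammaMax, object@fsLaw@hillN,
              object@fsLaw@kd))
  cat(sprintf("  Ca: rest %g nM, +%g/%g nM, tau %g/%g s\n", object@ca@cRest,
              object@ca@aFast, object@ca@aSlow, object@ca@tauFast,
              object@ca@tauSlow))
})

#' @export
setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d time points over %.3g s, %d APs\n",
              length(object@times), max(object@times),
              length(object@apTimes)))
  if (length(object@m))
    cat(sprintf("  m1 = %.3g, m_last = %.3g quanta; max xi = %.3g 1/s\n",
                object@m[1], object@m[length(object@m)], max(object@xi)))
})

#' @export
setMethod("show", "EventTrain", function(object) {
  cat(sprintf(
    "EventTrain: %d asynchronous events, %d sites, %.3g s (seed %g)\n",
    length(object@times), object@nSites, object@duration, object@seed))
  if (length(object@origin)) print(table(object@origin))
})

#' @export
setMethod("show", "ReleaseTensor", function(object) {
  d <- dim(object@m)
  cat(sprintf(
    "ReleaseTensor: %d synapses x %d frequencies x %d stimuli (%s Hz)\n",
    d[1], d[2], d[3], paste(object@freqs, collapse = ", ")))
})

#' @export
setMethod("show", "NtfResult", function(object) {
  cat(sprintf(
    "NtfResult: %d components, %d synapses; SSE = %.4g after %d iterations (%s)\n",
    ncol(object@amplitudes), nrow(object@amplitudes), object@sse,
    object@nIter, if (object@converged) "converged" else "not converged"))
})

#' @name accessors
#' @title Accessors for vesikit objects
#' @param object a vesikit S4 object
#' @param x a vesikit S4 object
#' @return the requested component
NULL

#' @rdname accessors
#' @export
setGeneric("quantalContents", function(object) standardGeneric("quantalContents"))
#' @rdname accessors
#' @export
setMethod("quantalContents", "Trajectory", function(object) object@m)
#' @rdname accessors
#' @export
setMethod("quantalContents", "EventTrain", function(object) object@mEvoked)

#' @rdname accessors
#' @export
setGeneric("occupancies", function(object) standardGeneric("occupancies"))
#' @rdname accessors
#' @export
setMethod("occupancies", "Trajectory", function(object) object@states)

#' @rdname accessors
#' @export
setGeneric("releaseRate", function(object) standardGeneric("releaseRate"))
#' @rdname accessors
#' @export
setMethod("releaseRate", "Trajectory", function(object) object@xi)
#' @rdname accessors
#' @export
setMethod("releaseRate", "RateTimecourse", function(object) object@rate)

#' @rdname accessors
#' @export
setGeneric("eventTimes", function(object) standardGeneric("eventTimes"))
#' @rdname accessors
#' @export
setMethod("eventTimes", "EventTrain", function(object) object@times)

#' @rdname accessors
#' @export
setGeneric("amplitudes", function(object) standardGeneric("amplitudes"))
#' @rdname accessors
#' @export
setMethod("amplitudes", "NtfResult", function(object) object@amplitudes)

#' @rdname accessors
#' @export
setGeneric("basefunctions", function(object) standardGeneric("basefunctions"))
#' @rdname accessors
#' @export
setMethod("basefunctions", "NtfResult", function(object) object@basefunctions)
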