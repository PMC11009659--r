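# Synthetic data generation: populations of heterogeneous synapses whose
# release trains come from the pinned kinetic model, and noisy current
# traces rendered from event trains with skewed quantal amplitudes.

#' Generate a synthetic synapse population and its release tensor
#'
#' Each synapse draws a resting TS pool size log-uniformly from
#' `spec@mtsRange` and scales its whole site complement proportionally, so
#' the fusion probability and state fractions are synapse-invariant and the
#' m1 vs M_TS relation stays exactly linear. On top of the overall scale,
#' the resting loose-state and empty-site occupancies are jittered
#' independently per synapse (lognormal, sd `jitterSd`): real synapses do
#' not sit
#' at an identical priming equilibrium, and without independent variation
#' of the pool composition the tensor would be rank-one across synapses
#' and its factorization into components unidentifiable. All trains are
#' simulated deterministically from the jittered initial state; each
#' quantal content receives multiplicative Gaussian noise of CV
#' `spec@quantalNoiseCv` (clipped at zero).
#'
#' @param spec a [PopulationSpec-class]
#' @param params a [ModelParams-class]
#' @param jitterSd lognormal SD of the per-synapse loose-pool and
#'   empty-site jitter (the printed pool sizes vary with a CV near 0.6
#'   across synapses)
#' @return list with `tensor` (a [ReleaseTensor-class]) and `groundTruth`
#'   (pFusion, per-synapse MTS / LS / ES / nTot, sAp)
#' @export
generatePopulation <- function(spec, params, jitterSd = 0.7) {
  set.seed(spec@seed)
  ss <- restingSteadyState(params)
  nSyn <- spec@nSynapses
  mts <- exp(stats::runif(nSyn, log(spec@mtsRange[1]),
                          log(spec@mtsRange[2])))
  scl <- mts / ss["ts"]
  lsJit <- stats::rlnorm(nSyn, 0, jitterSd)
  esJit <- stats::rlnorm(nSyn, 0, jitterSd)
  noise <- stats::rnorm(nSyn * length(spec@freqs) * spec@nAps)
  dim(noise) <- c(nSyn, length(spec@freqs), spec@nAps)

  m <- array(NA_real_, dim = c(nSyn, length(spec@freqs), spec@nAps))
  lsVec <- esVec <- fsVec <- numeric(nSyn)
  for (i in seq_len(nSyn)) {
    init <- c(es = ss["es"] * scl[i] * esJit[i],
              ls = ss["ls"] * scl[i] * lsJit[i],
              ts = mts[i], tsl = 0, fs = ss["fs"] * scl[i])
    lsVec[i] <- init[2]; esVec[i] <- init[1]; fsVec[i] <- init[5]
    for (f in seq_along(spec@freqs)) {
      traj <- simulateTrain(
        trainProtocol(spec@freqs[f], spec@nAps, tail = 0.01), params,
        dtOut = max(0.01, 0.2 / spec@freqs[f]), init = init)
      m[i, f, ] <- pmax(traj@m * (1 + spec@quantalNoiseCv * noise[i, f, ]),
                        0)
    }
  }
  tensor <- releaseTensor(m, spec@freqs,
                          synapseIds = sprintf("syn%02d", seq_len(nSyn)))
  list(tensor = tensor,
       groundTruth = list(pFusion = params@pFusion, mts = mts, ls = lsVec,
                          es = esVec, fs = fsVec,
                          nTot = mts + lsVec + esVec + fsVec,
                          sAp = params@sAp))
}

#' Render an event train into a noisy current trace
#'
#' Each event adds a difference-of-exponentials quantum (unit peak) scaled
#' by a beta-distributed amplitude; Gaussian noise is added. EPSCs are
#' negative-going. Ground-truth event times and amplitudes are kept on the
#' returned trace.
#'
#' @param events event times (s) or an [EventTrain-class]
#' @param wf a [QuantalWaveform-class]
#' @param noiseSd additive noise SD (pA)
#' @param dt sampling interval (s)
#' @param seed RNG seed
#' @param duration trace length (s); defaults to the event train duration
#'   or last event + 50 ms
#' @return a [CurrentTrace-class]
#' @export
synthesizeTrace <- function(events, wf, noiseSd = 2, dt = 2e-5, seed = 1,
                            duration = NULL) {
  times <- if (is(events, "EventTrain")) events@times else events
  if (is.null(duration))
    duration <- if (is(events, "EventTrain")) events@duration else
      if (length(times)) max(times) + 0.05 else 1
  set.seed(seed)
  n <- ceiling(duration / dt) + 1
  x <- if (noiseSd > 0) stats::rnorm(n, 0, noiseSd) else numeric(n)

  # unit-peak difference-of-exponentials kernel
  tPeak <- log(wf@decayTau / wf@riseTau) * wf@riseTau * wf@decayTau /
    (wf@decayTau - wf@riseTau)
  kLen <- ceiling((tPeak + 8 * wf@decayTau) / dt)
  kt <- (seq_len(kLen) - 1) * dt
  kern <- exp(-kt / wf@decayTau) - exp(-kt / wf@riseTau)
  kern <- kern / max(kern)

  amps <- wf@ampMax * stats::rbeta(length(times), wf@ampBetaA, wf@ampBetaB)
  for (e in seq_along(times)) {
    i0 <- floor(times[e] / dt) + 1
    idx <- i0:min(i0 + kLen - 1, n)
    x[idx] <- x[idx] - amps[e] * kern[seq_along(idx)]
  }
  currentTrace(x, dt, t0 = 0, trueEventTimes = times, trueAmps = amps)
}
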