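# Exact continuous-time Markov simulation of the scheme on the site-count
# vector. Sites are independent and identically distributed, so simulating
# aggregate counts (Gillespie) is equal in law to simulating each site;
# between APs the calcium transient only decays, hence every rate is
# non-increasing and the current total rate is an exact thinning bound
# (Ogata-style: bound refreshed after every accepted or rejected step).

.TRANSITIONS <- list(
  # from, to, fusion origin label (NA if not a fusion)
  list(f = 1L, t = 2L, lab = NA),        # es -> ls   (k1)
  list(f = 2L, t = 1L, lab = NA),        # ls -> es   (b1)
  list(f = 2L, t = 3L, lab = NA),        # ls -> ts   (k2)
  list(f = 3L, t = 2L, lab = NA),        # ts -> ls   (b2)
  list(f = 1L, t = 5L, lab = NA),        # es -> fs   (kf)
  list(f = 5L, t = 1L, lab = NA),        # fs -> es   (bf)
  list(f = 4L, t = 2L, lab = NA),        # tsl -> ls  (kUntight)
  list(f = 3L, t = 1L, lab = "TS"),      # ts fusion
  list(f = 4L, t = 1L, lab = "TSL"),     # tsl fusion
  list(f = 5L, t = 1L, lab = "FS"))      # fs fusion

.transRates <- function(params, n, c) {
  r <- .rateSet(params, c)
  c(r$k1 * n[1], params@b1 * n[2], r$k2 * n[2], params@b2 * n[3],
    r$kf * n[1], params@bf * n[5], params@kUntight * n[4],
    r$tsr * n[3], r$tsr * n[4], r$fsr * n[5])
}

#' Stochastic simulation of quantal release from independent docking sites
#'
#' Simulates the extended priming/fusion scheme as an exact continuous-time
#' Markov process over `nSites` docking sites, with the analytically known
#' calcium transient driving the time-varying rates (thinning against the
#' current total rate, which bounds the future rate between transitions
#' because calcium only decays there). At AP times each TS/TSL vesicle
#' fuses with probability `pFusion` (binomial draw) and a binomial fraction
#' `sAp` of LS converts to TSL. Asynchronous fusion events are returned
#' timestamped with their state of origin; AP-evoked synchronous fusion
#' counts are stored per stimulus.
#'
#' @param protocol a [StimulusProtocol-class]
#' @param params a [ModelParams-class]
#' @param nSites number of docking sites (initial occupancies are the
#'   resting steady state scaled to `nSites` and rounded stochastically)
#' @param seed integer RNG seed; identical inputs and seed give identical
#'   event trains
#' @param init optional integer occupancy vector overriding the resting
#'   start
#' @return an [EventTrain-class]
#' @export
simulateSites <- function(protocol, params, nSites = params@nTot, seed = 1,
                          init = NULL) {
  stopifnot(nSites >= 1)
  set.seed(seed)
  if (is.null(init)) {
    ss <- restingSteadyState(params) * nSites / params@nTot
    n <- floor(ss)
    # distribute the fractional remainder without biasing the mean
    rem <- ss - n
    extra <- nSites - sum(n)
    if (extra > 0) {
      idx <- sample.int(5, extra, replace = TRUE, prob = pmax(rem, 1e-12))
      for (i in idx) n[i] <- n[i] + 1
    }
  } else n <- as.numeric(init)
  stopifnot(sum(n) == nSites)

  ca <- params@ca
  aps <- protocol@apTimes
  bounds <- unique(c(0, aps, protocol@duration))
  Famp <- 0; Samp <- 0
  evTimes <- numeric(1024); evOrig <- character(1024); nEv <- 0L
  mEvoked <- numeric(length(aps))

  calcium <- function(t, t0) ca@cRest + Famp * exp(-(t - t0) / ca@tauFast) +
    Samp * exp(-(t - t0) / ca@tauSlow)

  for (k in seq_len(length(bounds) - 1)) {
    t0 <- bounds[k]; t1 <- bounds[k + 1]
    if (k > 1) {
      dt0 <- bounds[k] - bounds[k - 1]
      Famp <- Famp * exp(-dt0 / ca@tauFast)
      Samp <- Samp * exp(-dt0 / ca@tauSlow)
    }
    iAp <- match(t0, aps)
    if (!is.na(iAp)) {
      Famp <- Famp + ca@aFast
      Samp <- Samp + ca@aSlow
      fuseTs <- stats::rbinom(1, n[3], params@pFusion)
      fuseTsl <- stats::rbinom(1, n[4], params@pFusion)
      conv <- stats::rbinom(1, n[2] - 0, params@sAp)
      n[3] <- n[3] - fuseTs
      n[4] <- n[4] - fuseTsl + conv
      n[2] <- n[2] - conv
      n[1] <- n[1] + fuseTs + fuseTsl
      mEvoked[iAp] <- fuseTs + fuseTsl
    }
    t <- t0
    repeat {
      rates <- .transRates(params, n, calcium(t, t0))
      B <- sum(rates)
      if (B <= 0) break
      t <- t + stats::rexp(1, B)
      if (t >= t1) break
      ratesNow <- .transRates(params, n, calcium(t, t0))
      Rt <- sum(ratesNow)
      if (Rt > B + 1e-9 * B)
        stop("thinning bound violated")           # cannot happen: c decays
      if (stats::runif(1) <= Rt / B) {
        j <- sample.int(10, 1, prob = ratesNow)
        tr <- .TRANSITIONS[[j]]
        n[tr$f] <- n[tr$f] - 1
        n[tr$t] <- n[tr$t] + 1
        if (!is.na(tr$lab)) {
          nEv <- nEv + 1L
          if (nEv > length(evTimes)) {        # grow by doubling
            evTimes <- c(evTimes, numeric(length(evTimes)))
            evOrig <- c(evOrig, character(length(evOrig)))
          }
          evTimes[nEv] <- t
          evOrig[nEv] <- tr$lab
        }
      }
    }
  }
  evTimes <- evTimes[seq_len(nEv)]
  evOrig <- evOrig[seq_len(nEv)]
  new("EventTrain", times = evTimes, origin = evOrig, seed = seed,
      nSites = nSites, duration = protocol@duration, mEvoked = mEvoked,
      apTimes = aps)
}

#' Exponential fit to interevent intervals
#'
#' Maximum-likelihood exponential fit (the MLE of the time constant is the
#' sample mean interval) plus a binned interval histogram.
#'
#' @param events an [EventTrain-class] or numeric vector of event times
#' @param nBins histogram bins
#' @param minEvents minimum number of events required
#' @return list with `tau` (s), `rate` (1/s) and `histogram`
#'   (data.frame mid, counts)
#' @export
intereventFit <- function(events, nBins = 30, minEvents = 50) {
  times <- if (is(events, "EventTrain")) events@times else events
  if (length(times) < minEvents)
    stop(sprintf("need at least %d events for an interval fit", minEvents))
  iv <- diff(times)
  tau <- mean(iv)
  h <- graphics::hist(iv, breaks = nBins, plot = FALSE)
  list(tau = tau, rate = 1 / tau,
       histogram = data.frame(mid = h$mids, counts = h$counts))
}

#' Resting release rate and faulty-state occupancy versus the kf scaling
#'
#' For each value of the kf/k1 scaling factor sk, solves the resting steady
#' state and reports the deterministic spontaneous release rate together
#' with the faulty-state occupancy; optionally verifies each point with a
#' stochastic run.
#'
#' @param params a [ModelParams-class]
#' @param skValues scaling factors to evaluate
#' @param seed RNG seed for the optional stochastic verification
#' @param mcSeconds if > 0, also run a stochastic simulation of this length
#'   per sk and report the empirical event rate
#' @return data.frame with columns sk, nFs, rate (deterministic) and, if
#'   requested, rateMc
#' @export
skSweep <- function(params, skValues, seed = 1, mcSeconds = 0) {
  rows <- lapply(seq_along(skValues), function(i) {
    p <- setSk(params, skValues[i])
    ss <- restingSteadyState(p)
    cR <- p@ca@cRest
    rate <- evalFusionLaw(p@tsLaw, cR) * (ss["ts"] + ss["tsl"]) +
      evalFusionLaw(p@fsLaw, cR) * ss["fs"]
    row <- data.frame(sk = skValues[i], nFs = as.numeric(ss["fs"]),
                      rate = as.numeric(rate))
    if (mcSeconds > 0) {
      ev <- simulateSites(stimulusProtocol(numeric(0), mcSeconds), p,
                          seed = seed + i)
      row$rateMc <- length(ev@times) / mcSeconds
    }
    row
  })
  do.call(rbind, rows)
}
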