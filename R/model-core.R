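#' Effective global calcium concentration during a stimulus protocol
#'
#' Each AP adds an instantaneous increment that decays double-exponentially;
#' increments of successive APs superimpose linearly on the resting level.
#'
#' @param protocol a [StimulusProtocol-class] (an empty protocol is allowed)
#' @param ca a [CalciumParams-class]
#' @param t time(s) at which to evaluate (s); vectorised
#' @return concentration(s) in nM, never below `ca@cRest`
#' @examples
#' effectiveCalcium(stimulusProtocol(numeric(0), 1), calciumParams(), 0.3)
#' @export
effectiveCalcium <- function(protocol, ca, t) {
  stopifnot(all(t >= 0))
  out <- rep(ca@cRest, length(t))
  for (ti in protocol@apTimes) {
    d <- t - ti
    on <- d >= 0
    out[on] <- out[on] + ca@aFast * exp(-d[on] / ca@tauFast) +
      ca@aSlow * exp(-d[on] / ca@tauSlow)
  }
  out
}

#' Evaluate a Hill-type fusion rate law
#'
#' @param law a [FusionLaw-class]
#' @param c calcium concentration(s), nM; must be >= 0
#' @return fusion rate constant(s), 1/s
#' @examples
#' evalFusionLaw(fusionLaw(), 340)   # faulty-state law near its operating point
#' @export
evalFusionLaw <- function(law, c) {
  if (any(c < 0)) stop("negative calcium concentration")
  cn <- c^law@hillN
  law@basal + (law@gammaMax - law@basal) * cn / (cn + law@kd^law@hillN)
}

#' Evaluate a calcium-dependent priming rate law
#'
#' Saturating Michaelis-Menten-type increase above the resting rate:
#' monotone in calcium, equal to `kRest` at (or below) the activation
#' offset, approaching `kMax` at high calcium.
#'
#' @param law a [PrimingLaw-class]
#' @param c calcium concentration(s), nM
#' @return priming rate constant(s), 1/s
#' @export
evalPrimingRate <- function(law, c) {
  stopifnot(all(c >= 0))
  d <- pmax(c - law@c0, 0)
  law@kRest + (law@kMax - law@kRest) * d / (d + law@kHalf)
}
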