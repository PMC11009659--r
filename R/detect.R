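# Quantal event detection on current traces: low-pass filter, inverted
# first derivative, robust threshold, rising-edge crossings. EPSCs are
# negative-going, so the inverted derivative peaks at event onsets.

#' Detect quantal events on a current trace
#'
#' The trace is low-pass filtered (4-pole Butterworth, zero-phase), its
#' inverted first derivative computed, and events detected where that
#' derivative crosses `thresholdSd` times a robust baseline SD (median
#' absolute deviation, scaled) with a refractory separation of `minSep`.
#' The event time is the derivative peak within each crossing. Windows of
#' `blankLen` after each AP in `blankAps` are blanked before detection
#' (evoked synchronous responses are excluded, as in delayed-release
#' analysis).
#'
#' @param trace a [CurrentTrace-class]
#' @param cutoffHz low-pass cutoff (Hz)
#' @param thresholdSd threshold in baseline SDs
#' @param minSep minimum event separation (s)
#' @param blankAps AP times whose evoked responses are blanked (s)
#' @param blankLen blanking window length after each AP (s)
#' @param baselineWindow time window used for the baseline SD estimate (s);
#'   defaults to the whole (blanked) trace
#' @return numeric vector of event times (s)
#' @export
detectEvents <- function(trace, cutoffHz = 1000, thresholdSd = 4,
                         minSep = 1e-3, blankAps = numeric(0),
                         blankLen = 8e-3, baselineWindow = NULL) {
  fs <- 1 / trace@dt
  x <- trace@samples
  n <- length(x)
  if (n < 64) stop("trace shorter than the filter settling length")
  t <- trace@t0 + (seq_len(n) - 1) * trace@dt

  blank <- rep(FALSE, n)
  for (ap in blankAps)
    blank[t >= ap & t < ap + blankLen] <- TRUE
  if (any(blank)) {
    # hold the last pre-blank value through the blank to avoid filter edges
    xi <- x
    idx <- which(blank)
    runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
    for (r in runs) {
      pre <- if (min(r) > 1) xi[min(r) - 1] else xi[max(r) + 1]
      xi[r] <- pre
    }
    x <- xi
  }

  bf <- signal::butter(4, min(cutoffHz / (fs / 2), 0.99), type = "low")
  xf <- signal::filtfilt(bf, x)
  d <- -c(diff(xf), 0) / trace@dt          # inverted first derivative

  base <- if (is.null(baselineWindow)) d[!blank] else
    d[t >= baselineWindow[1] & t <= baselineWindow[2] & !blank]
  sdRob <- stats::mad(base, constant = 1.4826)
  # an (effectively) zero-variance baseline leaves no meaningful threshold
  if (sdRob <= 1e-9 * max(abs(d - stats::median(base)), 1))
    stop("zero-variance baseline")
  thr <- stats::median(base) + thresholdSd * sdRob

  above <- d > thr & !blank
  if (!any(above)) return(numeric(0))
  idx <- which(above)
  runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
  peaks <- vapply(runs, function(r) r[which.max(d[r])], numeric(1))
  peaks <- sort(peaks)
  # enforce minimum separation, keeping the earlier event
  keep <- c(TRUE, diff(peaks) * trace@dt >= minSep)
  while (!all(keep)) {
    peaks <- peaks[keep]
    keep <- c(TRUE, diff(peaks) * trace@dt >= minSep)
  }
  t[peaks]
}

#' Bin event times into a release rate timecourse
#'
#' @param events event times (s) or an [EventTrain-class]
#' @param bin bin width (s)
#' @param window c(start, end) of the binned range (s)
#' @return a [RateTimecourse-class]; rates satisfy
#'   sum(rate) * bin = number of events inside the window
#' @export
binRate <- function(events, bin = 0.02, window) {
  times <- if (is(events, "EventTrain")) events@times else events
  edges <- seq(window[1], window[2], by = bin)
  if (edges[length(edges)] < window[2])
    edges <- c(edges, edges[length(edges)] + bin)
  counts <- graphics::hist(times[times >= edges[1] &
                                   times < edges[length(edges)]],
                           breaks = edges, plot = FALSE, right = FALSE)$counts
  new("RateTimecourse", binEdges = edges, rate = counts / bin)
}

#' Mean release rates before and after a stimulus train
#'
#' Summarises a binned release timecourse relative to a protocol:
#' `ratePre` is the mean rate over the 2.5 s before the first AP,
#' `ratePost` the mean over 1 s starting 10 ms after the last AP, and
#' `nDelayed` the corresponding event count.
#'
#' @param xi a [RateTimecourse-class]
#' @param protocol a [StimulusProtocol-class]
#' @param preLen pre-train window length (s)
#' @param postStart offset of the post window after the last AP (s)
#' @param postLen post-train window length (s)
#' @return list with `ratePre`, `ratePost`, `nDelayed`
#' @export
prePostSummary <- function(xi, protocol, preLen = 2.5, postStart = 0.01,
                           postLen = 1) {
  if (!length(protocol@apTimes)) stop("protocol contains no APs")
  tFirst <- protocol@apTimes[1]
  tLast <- protocol@apTimes[length(protocol@apTimes)]
  mids <- (xi@binEdges[-1] + xi@binEdges[-length(xi@binEdges)]) / 2
  binw <- diff(xi@binEdges)
  pre <- mids >= tFirst - preLen & mids < tFirst
  post <- mids >= tLast + postStart & mids < tLast + postStart + postLen
  if (!any(pre) || !any(post))
    stop("binned window does not cover the pre/post analysis periods")
  list(ratePre = mean(xi@rate[pre]), ratePost = mean(xi@rate[post]),
       nDelayed = sum(xi@rate[post] * binw[post]))
}
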