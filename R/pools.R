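# Classical train-based estimators of the fast-releasable pool (FRP):
# cumulative back-extrapolation, correction of 1/FRP vs interstimulus
# interval for incomplete depletion, and geometric-series fits.

#' Apparent pool size by cumulative back-extrapolation
#'
#' Fits an ordinary least-squares line to the last `lastK` points of the
#' cumulative quantal content over stimulus index and returns its intercept
#' at stimulus index 0: the depletable (fast-releasable) pool apparent at
#' this stimulation frequency.
#'
#' @param mj quantal contents of one train
#' @param lastK number of tail responses used for the regression
#' @return list with `frp` (intercept), `slope` (steady-state quanta per
#'   stimulus) and `r2`
#' @export
frpBackextrapolate <- function(mj, lastK = 5) {
  n <- length(mj)
  if (n <= lastK) stop("train must be longer than lastK")
  cum <- cumsum(mj)
  j <- seq_len(n)
  sel <- (n - lastK + 1):n
  fit <- stats::lm(cum[sel] ~ j[sel])
  tss <- sum((cum[sel] - mean(cum[sel]))^2)
  r2 <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else 1
  list(frp = as.numeric(stats::coef(fit)[1]),
       slope = as.numeric(stats::coef(fit)[2]), r2 = r2)
}

#' Correct apparent pool sizes for incomplete depletion
#'
#' Regresses 1/FRP on the interstimulus interval and returns the inverse of
#' the intercept: the pool size extrapolated to an infinitely fast train,
#' where recovery between stimuli vanishes.
#'
#' @param frpByFreq apparent pool sizes
#' @param isis corresponding interstimulus intervals (s)
#' @return list with `frp` (corrected pool), `intercept`, `slope` and `r2`
#'   of the inverse regression
#' @export
frpIsiCorrect <- function(frpByFreq, isis) {
  stopifnot(length(frpByFreq) == length(isis), length(isis) >= 2)
  y <- 1 / frpByFreq
  fit <- stats::lm(y ~ isis)
  ic <- as.numeric(stats::coef(fit)[1])
  if (ic <= 0) stop("non-positive 1/FRP intercept; cannot invert")
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else 1
  list(frp = 1 / ic, intercept = ic,
       slope = as.numeric(stats::coef(fit)[2]), r2 = r2)
}

#' Convenience wrapper: simulate trains and estimate the corrected FRP
#'
#' Simulates 40-AP trains at the given frequencies from a parameter set,
#' back-extrapolates the cumulative quantal content per frequency and
#' applies the interstimulus-interval correction.
#'
#' @param params a [ModelParams-class]
#' @param freqs train frequencies (Hz)
#' @param nAps APs per train
#' @param lastK tail points for the per-frequency regression
#' @return list with `corrected` (pool size), `apparent` (data.frame freq,
#'   isi, frp) and the inverse-regression diagnostics
#' @export
frpFromModel <- function(params, freqs = c(50, 100, 200), nAps = 40,
                         lastK = 5) {
  app <- vapply(freqs, function(f) {
    traj <- simulateTrain(trainProtocol(f, nAps, tail = 0.01), params,
                          dtOut = max(0.005, 0.1 / f))
    frpBackextrapolate(traj@m, lastK)$frp
  }, numeric(1))
  isis <- 1 / freqs
  corr <- frpIsiCorrect(app, isis)
  list(corrected = corr$frp,
       apparent = data.frame(freq = freqs, isi = isis, frp = app),
       regression = corr)
}

#' Geometric-series fit of a quantal content train
#'
#' Nonlinear least squares of m_j = p * (1-p)^(j-1) * M over the fusion
#' probability p and pool size M: the depletion model with constant fusion
#' probability and no replenishment.
#'
#' @param mj quantal contents
#' @return list with `pFusion`, `m` (pool size) and the residual sum of
#'   squares
#' @export
geometricFit <- function(mj) {
  j <- seq_along(mj)
  p0 <- if (length(mj) >= 2 && mj[1] > 0 && mj[2] > 0)
    min(max(1 - mj[2] / mj[1], 0.05), 0.95) else 0.3
  M0 <- max(sum(mj), mj[1] / p0)
  obj <- function(theta) {
    p <- stats::plogis(theta[1]); M <- exp(theta[2])
    sum((mj - p * (1 - p)^(j - 1) * M)^2)
  }
  fit <- stats::optim(c(stats::qlogis(p0), log(M0)), obj,
                      method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  list(pFusion = stats::plogis(fit$par[1]), m = exp(fit$par[2]),
       rss = fit$value)
}

#' Nonparametric bootstrap over synapses
#'
#' Resamples synapses with replacement and re-evaluates a statistic, giving
#' a bootstrap standard error for population-level estimates.
#'
#' @param tensor a [ReleaseTensor-class]
#' @param statistic function taking a [ReleaseTensor-class] and returning a
#'   single number
#' @param nBoot resamples
#' @param seed RNG seed
#' @return list with `se`, `estimates`
#' @export
bootstrapSynapses <- function(tensor, statistic, nBoot = 1000, seed = 1) {
  set.seed(seed)
  nI <- dim(tensor@m)[1]
  est <- vapply(seq_len(nBoot), function(b) {
    idx <- sample.int(nI, nI, replace = TRUE)
    sub <- releaseTensor(tensor@m[idx, , , drop = FALSE], tensor@freqs,
                         mask = tensor@mask[idx, , , drop = FALSE],
                         nAps = tensor@nAps,
                         synapseIds = paste0("b", seq_len(nI)))
    statistic(sub)
  }, numeric(1))
  list(se = stats::sd(est), estimates = est)
}
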