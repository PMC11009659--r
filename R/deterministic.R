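# Mean-field simulation of the extended priming/fusion scheme.
# Between APs the occupancies follow a linear ODE whose rates depend on the
# analytically known calcium transient; at each AP an exact discrete jump is
# applied (fusion of TS/TSL with probability pFusion, LS->TSL conversion).

.rateSet <- function(params, c) {
  list(k1 = evalPrimingRate(params@priming1, c),
       k2 = evalPrimingRate(params@priming2, c),
       kf = evalPrimingRate(params@primingF, c),
       tsr = evalFusionLaw(params@tsLaw, c),
       fsr = evalFusionLaw(params@fsLaw, c))
}

# flow matrix Q such that dy/dt = Q %*% y at fixed calcium
.flowMatrix <- function(params, c) {
  r <- .rateSet(params, c)
  b1 <- params@b1; b2 <- params@b2; bf <- params@bf; ku <- params@kUntight
  Q <- matrix(0, 5, 5, dimnames = list(.STATES, .STATES))
  Q["es", "es"] <- -(r$k1 + r$kf)
  Q["ls", "es"] <- r$k1
  Q["fs", "es"] <- r$kf
  Q["es", "ls"] <- b1
  Q["ls", "ls"] <- -(b1 + r$k2)
  Q["ts", "ls"] <- r$k2
  Q["ls", "ts"] <- b2
  Q["ts", "ts"] <- -(b2 + r$tsr)
  Q["es", "ts"] <- r$tsr
  Q["ls", "tsl"] <- ku
  Q["es", "tsl"] <- r$tsr
  Q["tsl", "tsl"] <- -(ku + r$tsr)
  Q["es", "fs"] <- bf + r$fsr
  Q["fs", "fs"] <- -(bf + r$fsr)
  Q
}

#' Resting steady state of the kinetic scheme
#'
#' Solves the linear balance at resting calcium under the site-conservation
#' constraint (the scheme is closed: fused vesicles free their sites).
#'
#' @param params a [ModelParams-class]
#' @return named numeric occupancy vector (es, ls, ts, tsl, fs)
#' @export
restingSteadyState <- function(params) {
  Q <- .flowMatrix(params, params@ca@cRest)
  A <- Q
  A[5, ] <- 1                        # replace one balance by conservation
  y <- solve(A, c(0, 0, 0, 0, params@nTot))
  res <- max(abs(Q %*% y))
  if (res > 1e-9 * params@nTot)
    stop(sprintf("steady state did not converge (residual %.3g)", res))
  stats::setNames(as.numeric(y), .STATES)
}

#' Apply the discrete per-AP jump map
#'
#' Fuses TS and TSL vesicles with probability `pFusion` (fused sites return
#' to ES) and converts the fraction `sAp` of LS to the labile tight state
#' TSL. Site conservation is exact.
#'
#' @param state named occupancy vector (es, ls, ts, tsl, fs)
#' @param params a [ModelParams-class]
#' @return list with elements `state` (post-AP occupancies) and `m`
#'   (quantal content of the AP)
#' @export
applyAp <- function(state, params) {
  p <- params@pFusion
  m <- p * (state["ts"] + state["tsl"])
  conv <- params@sAp * state["ls"]
  state["es"] <- state["es"] + m
  state["ts"] <- state["ts"] * (1 - p)
  state["tsl"] <- state["tsl"] * (1 - p) + conv
  state["ls"] <- state["ls"] - conv
  list(state = state, m = as.numeric(m))
}

.odeRhs <- function(t, y, parms) {
  c <- parms$cRest + parms$Famp * exp(-(t - parms$t0) / parms$tauFast) +
    parms$Samp * exp(-(t - parms$t0) / parms$tauSlow)
  p <- parms$params
  r <- .rateSet(p, c)
  es <- y[1]; ls <- y[2]; ts <- y[3]; tsl <- y[4]; fs <- y[5]
  rel <- r$tsr * (ts + tsl) + r$fsr * fs
  des <- -(r$k1 + r$kf) * es + p@b1 * ls + p@bf * fs + rel
  dls <- r$k1 * es - (p@b1 + r$k2) * ls + p@b2 * ts + p@kUntight * tsl
  dts <- r$k2 * ls - (p@b2 + r$tsr) * ts
  dtsl <- -(p@kUntight + r$tsr) * tsl
  dfs <- r$kf * es - (p@bf + r$fsr) * fs
  list(c(des, dls, dts, dtsl, dfs))
}

#' Simulate the mean-field response to a stimulus protocol
#'
#' Integrates the scheme between APs with an adaptive stiff-capable solver
#' (lsoda, rtol 1e-8, atol 1e-10) and applies the exact AP jump map at each
#' stimulus. Records per-AP quantal contents, occupancies, the calcium
#' transient and the asynchronous release rate
#' xi(t) = tsRate(ca) * (TS + TSL) + fsRate(ca) * FS on the output grid.
#' Occupancies reported at AP times are pre-jump values.
#'
#' @param protocol a [StimulusProtocol-class]
#' @param params a [ModelParams-class]
#' @param dtOut output grid spacing (s)
#' @param init optional initial occupancy vector; defaults to the resting
#'   steady state
#' @return a [Trajectory-class]
#' @export
simulateTrain <- function(protocol, params, dtOut = 1e-3, init = NULL) {
  stopifnot(dtOut > 0)
  state <- if (is.null(init)) restingSteadyState(params) else
    stats::setNames(as.numeric(init), .STATES)
  ca <- params@ca
  aps <- protocol@apTimes
  bounds <- unique(c(0, aps, protocol@duration))
  grid <- seq(0, protocol@duration, by = dtOut)

  Famp <- 0; Samp <- 0; tPrev <- 0
  m <- numeric(length(aps))
  times <- ca_out <- xi_out <- numeric(0)
  states <- NULL

  for (k in seq_len(length(bounds) - 1)) {
    t0 <- bounds[k]; t1 <- bounds[k + 1]
    # decay residual calcium amplitudes to the segment start
    Famp <- Famp * exp(-(t0 - tPrev) / ca@tauFast)
    Samp <- Samp * exp(-(t0 - tPrev) / ca@tauSlow)
    tPrev <- t0
    iAp <- match(t0, aps)
    if (!is.na(iAp)) {
      Famp <- Famp + ca@aFast
      Samp <- Samp + ca@aSlow
      jump <- applyAp(state, params)
      state <- jump$state
      m[iAp] <- jump$m
    }
    eps <- 1e-9 * max(1, t1)
    segTimes <- unique(c(t0, grid[grid > t0 + eps & grid < t1 - eps], t1))
    parms <- list(params = params, cRest = ca@cRest, Famp = Famp,
                  Samp = Samp, t0 = t0, tauFast = ca@tauFast,
                  tauSlow = ca@tauSlow)
    sol <- deSolve::ode(y = as.numeric(state), times = segTimes,
                        func = .odeRhs, parms = parms, method = "lsoda",
                        rtol = 1e-8, atol = 1e-10)
    y <- sol[, -1, drop = FALSE]
    if (min(y) < -1e-6 * params@nTot)
      stop("integration produced negative occupancies beyond tolerance")
    y[y < 0] <- 0
    cseg <- parms$cRest + Famp * exp(-(segTimes - t0) / ca@tauFast) +
      Samp * exp(-(segTimes - t0) / ca@tauSlow)
    tsr <- evalFusionLaw(params@tsLaw, cseg)
    fsr <- evalFusionLaw(params@fsLaw, cseg)
    xiseg <- tsr * (y[, 3] + y[, 4]) + fsr * y[, 5]
    keep <- if (k < length(bounds) - 1)
      seq_len(length(segTimes) - 1) else seq_along(segTimes)
    times <- c(times, segTimes[keep])
    states <- rbind(states, y[keep, , drop = FALSE])
    ca_out <- c(ca_out, cseg[keep])
    xi_out <- c(xi_out, xiseg[keep])
    state <- stats::setNames(y[nrow(y), ], .STATES)
  }
  colnames(states) <- .STATES
  new("Trajectory", times = times, states = states, ca = ca_out,
      xi = xi_out, m = m, apTimes = aps)
}

#' Steady-state quantal content across stimulation frequencies
#'
#' Simulates one train per frequency and summarises the initial quantal
#' content m1, the steady-state content m_ss (mean of the last five in-train
#' responses) and the relative depression 1 - m_ss/m1.
#'
#' @param params a [ModelParams-class]
#' @param freqs stimulation frequencies (Hz)
#' @param nAps APs per train
#' @return data.frame with columns freq, m1, mss, depression
#' @export
frequencySweep <- function(params, freqs, nAps = 40) {
  res <- lapply(freqs, function(f) {
    traj <- simulateTrain(trainProtocol(f, nAps, tail = 0.01), params,
                          dtOut = max(0.01, 0.2 / f))
    m <- traj@m
    mss <- mean(utils::tail(m, 5))
    data.frame(freq = f, m1 = m[1], mss = mss,
               depression = 1 - mss / m[1])
  })
  do.call(rbind, res)
}

#' Test-AP probe of the delayed release timecourse
#'
#' Runs a conditioning train (default 15 APs at 100 Hz) with and without an
#' additional single test AP 200 ms after the last conditioning stimulus and
#' compares the delayed release rate xi(t) after the test AP. A small
#' fractional change indicates that the test AP consumes few of the
#' vesicles carrying delayed release.
#'
#' @param params a [ModelParams-class]
#' @param freqHz,nAps conditioning train
#' @param testDelay delay of the test AP after the last conditioning AP (s)
#' @param window time window after the test AP over which xi is integrated
#'   (s, relative to protocol start)
#' @param dtOut output grid spacing (s)
#' @return list with both [Trajectory-class] objects, the xi integrals over
#'   the window and their fractional difference
#' @export
testApProtocol <- function(params, freqHz = 100, nAps = 15,
                           testDelay = 0.2, window = NULL, dtOut = 1e-3) {
  tLast <- (nAps - 1) / freqHz
  tTest <- tLast + testDelay
  if (is.null(window)) window <- c(tTest + 0.01, 1)
  dur <- max(window[2], tTest) + 0.2
  apsCond <- (seq_len(nAps) - 1) / freqHz
  withTest <- simulateTrain(stimulusProtocol(c(apsCond, tTest), dur),
                            params, dtOut)
  withoutTest <- simulateTrain(stimulusProtocol(apsCond, dur), params,
                               dtOut)
  inWin <- function(traj) {
    sel <- traj@times >= window[1] & traj@times <= window[2]
    sum(traj@xi[sel]) * dtOut
  }
  iW <- inWin(withTest); iWo <- inWin(withoutTest)
  list(withTest = withTest, withoutTest = withoutTest,
       integralWith = iW, integralWithout = iWo,
       fractionalChange = (iW - iWo) / iWo)
}
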