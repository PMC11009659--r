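test_that("resting steady state balances fluxes and conserves sites", {
  p <- toyParams()
  ss <- restingSteadyState(p)
  expect_equal(sum(ss), p@nTot, tolerance = 1e-9)
  expect_true(all(ss >= 0))
  # no access to the faulty state -> empty faulty pool
  p0 <- setSk(p, 0)
  expect_equal(as.numeric(restingSteadyState(p0)["fs"]), 0, tolerance = 1e-9)
})

test_that("the AP jump map releases p*(TS+TSL) and conserves sites", {
  p <- toyParams()
  s <- c(es = 100, ls = 200, ts = 150, tsl = 30, fs = 20)
  out <- applyAp(s, p)
  expect_equal(out$m, p@pFusion * (150 + 30))
  expect_equal(sum(out$state), sum(s))
  set.seed(7)
  for (i in 1:10) {
    s <- stats::setNames(stats::runif(5, 0, 500),
                         c("es", "ls", "ts", "tsl", "fs"))
    expect_equal(sum(applyAp(s, p)$state), sum(s), tolerance = 1e-12)
  }
  pz <- frozenParams(p = 0)
  expect_equal(applyAp(s, pz)$state, s)
  expect_equal(applyAp(s, pz)$m, 0)
})

test_that("site conservation holds along simulated trajectories", {
  p <- toyParams()
  traj <- simulateTrain(trainProtocol(20, 10, tail = 0.3), p, dtOut = 5e-3)
  expect_true(all(abs(rowSums(traj@states) - p@nTot) < 1e-6 * p@nTot))
  expect_true(all(traj@xi >= 0))
  # xi identity on the grid
  tsr <- evalFusionLaw(p@tsLaw, traj@ca)
  fsr <- evalFusionLaw(p@fsLaw, traj@ca)
  xi2 <- tsr * (traj@states[, "ts"] + traj@states[, "tsl"]) +
    fsr * traj@states[, "fs"]
  expect_equal(traj@xi, xi2, tolerance = 1e-10)
})

test_that("with priming frozen the train is an exact geometric series", {
  M <- 656; pfus <- 0.48
  p <- frozenParams(p = pfus)
  traj <- simulateTrain(trainProtocol(20, 15, tail = 0.01), p,
                        dtOut = 1e-3, init = c(0, 0, M, 0, 0))
  j <- seq_len(15)
  expect_equal(traj@m, pfus * (1 - pfus)^(j - 1) * M, tolerance = 1e-9)
  # monotone depletion of the tight pool
  expect_true(all(diff(traj@states[, "ts"]) <= 1e-9))
})

test_that("quantal contents are insensitive to the output grid", {
  p <- toyParams()
  m1 <- simulateTrain(trainProtocol(50, 8, tail = 0.05), p, dtOut = 2e-3)@m
  m2 <- simulateTrain(trainProtocol(50, 8, tail = 0.05), p, dtOut = 1e-3)@m
  expect_equal(m1, m2, tolerance = 1e-3 * 0.001)
})

test_that("steady-state content approaches the initial content as f -> 0", {
  p <- toyParams()
  sw <- frequencySweep(p, 0.05, 8)
  expect_lt(abs(sw$depression), 0.05)
})

test_that("a lone AP leaves the release rate back at its resting level", {
  p <- defaultParams("ko")
  traj <- simulateTrain(stimulusProtocol(0.05, 6), p, dtOut = 5e-3)
  restXi <- traj@xi[1]
  endXi <- traj@xi[length(traj@xi)]
  expect_lt(abs(endXi - restXi) / restXi, 0.05)
})

test_that("a test AP 200 ms after the train barely alters delayed release", {
  p <- defaultParams("ko")
  out <- testApProtocol(p, dtOut = 2e-3)
  expect_lt(abs(out$fractionalChange), 0.15)
})
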