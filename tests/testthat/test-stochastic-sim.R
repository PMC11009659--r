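test_that("a silent model produces no events and seeds are reproducible", {
  p <- frozenParams(p = 0)
  ev <- simulateSites(stimulusProtocol(numeric(0), 5), p, nSites = 100,
                      seed = 3, init = c(20, 20, 20, 20, 20))
  expect_length(ev@times, 0)

  q <- toyParams()
  e1 <- simulateSites(stimulusProtocol(c(0.1, 0.2), 1), q, nSites = 200,
                      seed = 11)
  e2 <- simulateSites(stimulusProtocol(c(0.1, 0.2), 1), q, nSites = 200,
                      seed = 11)
  expect_identical(e1@times, e2@times)
  expect_identical(e1@origin, e2@origin)
  expect_identical(e1@mEvoked, e2@mEvoked)
  e3 <- simulateSites(stimulusProtocol(c(0.1, 0.2), 1), q, nSites = 200,
                      seed = 12)
  expect_false(identical(e1@times, e3@times))
})

test_that("a collapsed constant-rate model emits Poisson event counts", {
  # sites fuse at a constant rate and recycle almost instantly, so binned
  # counts of one long run follow a Poisson law
  rate <- 1; N <- 30; T <- 120
  ev <- simulateSites(stimulusProtocol(numeric(0), T),
                      poissonParams(rate, N), nSites = N, seed = 5,
                      init = c(0, 0, N, 0, 0))
  binw <- 2
  counts <- graphics::hist(ev@times, breaks = seq(0, T, binw),
                           plot = FALSE)$counts
  lambda <- mean(counts)
  expect_equal(lambda, rate * N * binw, tolerance = 0.15)
  # index of dispersion ~ 1 for Poisson; chi-square bounds at alpha=0.01
  disp <- stats::var(counts) / lambda * (length(counts) - 1)
  expect_gt(disp, stats::qchisq(0.005, length(counts) - 1))
  expect_lt(disp, stats::qchisq(0.995, length(counts) - 1))
})

test_that("ensemble event rate matches the deterministic resting rate", {
  p <- toyParams()
  ss <- restingSteadyState(p)
  rateDet <- evalFusionLaw(p@tsLaw, 50) * (ss["ts"] + ss["tsl"]) +
    evalFusionLaw(p@fsLaw, 50) * ss["fs"]
  T <- 100
  ev <- simulateSites(stimulusProtocol(numeric(0), T), p, seed = 21)
  n <- length(ev@times)
  expect_lt(abs(n - rateDet * T) / sqrt(rateDet * T), 3)
})

test_that("interevent fitting recovers exponential time constants", {
  set.seed(99)
  t1 <- cumsum(stats::rexp(1000, 5))
  fit <- intereventFit(t1)
  expect_lt(abs(fit$tau - 0.2), 2 * 0.2 / sqrt(1000))
  # superposition of two Poisson trains
  t2 <- sort(c(t1, cumsum(stats::rexp(600, 3))[cumsum(stats::rexp(600, 3)) <
                                                  max(t1)]))
  fit2 <- intereventFit(t2)
  expect_equal(fit2$tau, 1 / 8, tolerance = 0.1)
  expect_error(intereventFit(t1[1:10]), "at least")
})

test_that("resting interevent intervals are exponential (KS, alpha 0.01)", {
  p <- defaultParams("ko")
  ev <- simulateSites(stimulusProtocol(numeric(0), 90), p, seed = 17)
  iv <- diff(ev@times)
  expect_gt(length(iv), 100)
  ks <- stats::ks.test(iv, "pexp", 1 / mean(iv))
  expect_gt(ks$p.value, 0.01)
})

test_that("spontaneous release grows with the faulty-state access rate", {
  p <- defaultParams("ko")
  sw <- skSweep(p, c(0, 0.065, 0.2, 0.65))
  expect_equal(sw$nFs[1], 0, tolerance = 1e-9)
  expect_true(all(diff(sw$rate) > 0))
  # the wild-type resting rate lies between the sk = 0.065 and sk = 0.65
  # predictions
  wtRate <- 5.14
  expect_lt(sw$rate[2], wtRate)
  expect_gt(sw$rate[4], wtRate)
})
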