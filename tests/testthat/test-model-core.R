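test_that("effective calcium is resting level without APs and decays back", {
  ca <- calciumParams()
  none <- stimulusProtocol(numeric(0), 1)
  expect_equal(effectiveCalcium(none, ca, c(0, 0.3, 0.9)), rep(50, 3))

  one <- stimulusProtocol(0.1, 60)
  tFar <- 0.1 + 100 * max(ca@tauFast, ca@tauSlow)
  expect_equal(effectiveCalcium(one, ca, tFar), 50, tolerance = 1e-6)
  # instantaneous rise: just after the AP the full increment is present
  expect_equal(effectiveCalcium(one, ca, 0.1), 50 + ca@aFast + ca@aSlow)
})

test_that("calcium transients superimpose linearly above baseline", {
  ca <- calciumParams(50, 100, 30, 0.03, 0.25)
  a <- stimulusProtocol(c(0.05, 0.21), 2)
  b <- stimulusProtocol(c(0.1, 0.4, 0.55), 2)
  ab <- stimulusProtocol(sort(c(a@apTimes, b@apTimes)), 2)
  t <- seq(0, 2, by = 0.013)
  lhs <- effectiveCalcium(ab, ca, t)
  rhs <- effectiveCalcium(a, ca, t) + effectiveCalcium(b, ca, t) - 50
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("fusion law reproduces Hill behaviour", {
  fs <- fusionLaw(0, 2.72, 3.4, 107)
  # half-maximum at the apparent KD when there is no basal rate
  expect_equal(evalFusionLaw(fs, 107), 2.72 / 2, tolerance = 1e-12)
  # saturation
  expect_equal(evalFusionLaw(fs, 1e9), 2.72, tolerance = 1e-4)
  expect_error(evalFusionLaw(fs, -1), "negative")
})

test_that("fusion and priming laws are monotone in calcium", {
  set.seed(42)
  grid <- sort(stats::runif(40, 0, 5000))
  for (rep in 1:20) {
    b <- stats::runif(1, 0, 0.5)
    law <- fusionLaw(b, b + stats::runif(1, 0.1, 10),
                     stats::runif(1, 0.5, 5), stats::runif(1, 20, 2000))
    expect_true(all(diff(evalFusionLaw(law, grid)) >= -1e-12))
    kr <- stats::runif(1, 0, 2)
    pl <- primingLaw(kr, kr + stats::runif(1, 0, 10),
                     stats::runif(1, 5, 2000))
    v <- evalPrimingRate(pl, grid)
    expect_true(all(diff(v) >= -1e-12))
    expect_equal(evalPrimingRate(pl, pl@c0), kr)
    expect_equal(evalPrimingRate(pl, 1e12), pl@kMax, tolerance = 1e-6)
  }
})

test_that("the faulty-state law is tied to the first priming step at rest", {
  p <- toyParams()
  expect_equal(p@primingF@kRest, p@sk * p@priming1@kRest)
  p2 <- setSk(p, 0.2)
  expect_equal(p2@primingF@kRest, 0.2 * p2@priming1@kRest)
  expect_equal(p2@primingF@kMax / p@primingF@kMax, 0.2 / 0.05)
})

test_that("resting fusogenicity of faulty vesicles exceeds tight-state one", {
  # with the fitted Hill parameters the margin is over an order of
  # magnitude for both genotypes
  for (g in c("wt", "ko")) {
    p <- defaultParams(g)
    ratio <- evalFusionLaw(p@fsLaw, 50) / evalFusionLaw(p@tsLaw, 50)
    expect_gt(ratio, 10)
  }
})

test_that("parameter validity is enforced", {
  expect_error(calciumParams(aFast = 150, aSlow = 60), "200")
  expect_error(fusionLaw(basal = 1, gammaMax = 0.5), "exceed")
  expect_error(primingLaw(0.5, 0.1), "kRest")
  expect_error(stimulusProtocol(c(0.2, 0.1), 1), "increasing")
})
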