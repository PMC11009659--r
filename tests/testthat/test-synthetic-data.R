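test_that("a noise-free unit-scale population equals the direct simulation", {
  p <- toyParams()
  ss <- restingSteadyState(p)
  spec <- populationSpec(nSynapses = 2,
                         mtsRange = ss["ts"] * c(1, 1 + 1e-9),
                         quantalNoiseCv = 0, freqs = c(10, 50), nAps = 12,
                         seed = 1)
  pop <- generatePopulation(spec, p, jitterSd = 0)
  for (f in seq_along(spec@freqs)) {
    direct <- simulateTrain(trainProtocol(spec@freqs[f], 12, tail = 0.01),
                            p, dtOut = max(0.01, 0.2 / spec@freqs[f]))@m
    expect_equal(as.numeric(pop$tensor@m[1, f, ]), direct,
                 tolerance = 1e-6)
  }
})

test_that("population generation is a pure function of spec and seed", {
  p <- toyParams()
  spec <- populationSpec(nSynapses = 3, mtsRange = c(100, 400),
                         freqs = c(10, 50), nAps = 10, seed = 7)
  a <- generatePopulation(spec, p)
  b <- generatePopulation(spec, p)
  expect_identical(a$tensor@m, b$tensor@m)
  spec2 <- populationSpec(nSynapses = 3, mtsRange = c(100, 400),
                          freqs = c(10, 50), nAps = 10, seed = 8)
  c <- generatePopulation(spec2, p)
  expect_false(identical(a$tensor@m, c$tensor@m))
})

test_that("the default wild-type population matches the printed pool scale", {
  pop <- generatePopulation(populationSpec(seed = 1), defaultParams("wt"))
  expect_lt(abs(mean(pop$groundTruth$mts) - 656) / 656, 0.2)
  expect_true(all(pop$groundTruth$mts >= 110 & pop$groundTruth$mts <= 1571))
  # linearity of first response in the tight pool size (exact, cv folded in)
  m1 <- rowMeans(pop$tensor@m[, , 1])
  fit <- stats::lm(m1 ~ pop$groundTruth$mts)
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("trace synthesis renders quanta with the requested peaks", {
  wf <- quantalWaveform()
  z <- synthesizeTrace(numeric(0), wf, noiseSd = 0, duration = 0.1)
  expect_true(all(z@samples == 0))
  one <- synthesizeTrace(0.02, wf, noiseSd = 0, duration = 0.1, seed = 3)
  expect_equal(-min(one@samples), one@trueAmps[1], tolerance = 0.01)
  # beta amplitudes have the requested mean
  set.seed(1)
  many <- synthesizeTrace(sort(stats::runif(400, 0, 4)), wf, noiseSd = 0,
                          duration = 4.1, seed = 5)
  expect_equal(mean(many@trueAmps), wf@meanAmp, tolerance = 0.1 * wf@meanAmp)
})

test_that("stochastic events round-trip through rendering and detection", {
  p <- defaultParams("ko")
  ev <- simulateSites(stimulusProtocol(numeric(0), 20), p, seed = 41)
  expect_gt(length(ev@times), 30)
  tr <- synthesizeTrace(ev, quantalWaveform(), noiseSd = 3, dt = 2e-5,
                        seed = 42)
  det <- detectEvents(tr)
  recall <- mean(vapply(ev@times, function(t0) any(abs(det - t0) < 1.5e-3),
                        logical(1)))
  expect_gt(recall, 0.9)
  xi <- binRate(det, 0.5, c(0, 20))
  expect_equal(mean(xi@rate), length(ev@times) / 20, tolerance = 0.15)
})
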