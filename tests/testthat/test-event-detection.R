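wfDefault <- quantalWaveform()

test_that("noise-only traces yield almost no detections", {
  set.seed(31)
  fp <- replicate(10, {
    tr <- currentTrace(stats::rnorm(1e5, 0, 2), dt = 2e-5)
    length(detectEvents(tr)) / 2          # events per second
  })
  expect_lt(mean(fp), 0.5)
})

test_that("a single clean quantum is found once, at its onset", {
  tr <- synthesizeTrace(0.5, wfDefault, noiseSd = 1.5, dt = 2e-5,
                        seed = 1, duration = 1)
  ev <- detectEvents(tr, thresholdSd = 6)
  expect_length(ev, 1)
  expect_lt(abs(ev - 0.5), 1e-4)
  # a constant trace has no baseline variance at all
  expect_error(detectEvents(currentTrace(rep(1, 5000), 2e-5)), "baseline")
})

test_that("detection commutes with time shifts", {
  set.seed(5)
  base <- synthesizeTrace(c(0.2, 0.45, 0.8), wfDefault, noiseSd = 1,
                          dt = 2e-5, seed = 9, duration = 1.2)
  k <- 500
  shifted <- currentTrace(c(base@samples[1:k] * 0 + base@samples[1],
                            base@samples[1:(length(base@samples) - k)]),
                          dt = base@dt)
  e0 <- detectEvents(base)
  e1 <- detectEvents(shifted)
  expect_length(e1, length(e0))
  expect_equal(e1, e0 + k * base@dt, tolerance = 1e-4)
})

test_that("binned rates conserve event counts", {
  expect_equal(sum(binRate(numeric(0), 0.02, c(0, 1))@rate), 0)
  set.seed(2)
  ev <- sort(stats::runif(10, 0.01, 0.99))
  for (bw in c(0.02, 0.05, 0.25)) {
    rt <- binRate(ev, bw, c(0, 1))
    expect_equal(sum(rt@rate) * bw, 10, tolerance = 1e-9)
  }
})

test_that("stationary input gives equal pre and post rates", {
  set.seed(12)
  ev <- cumsum(stats::rexp(4000, 20))
  prot <- stimulusProtocol(c(3.0, 3.1), 10)
  xi <- binRate(ev, 0.02, c(0, 10))
  s <- prePostSummary(xi, prot)
  expect_equal(s$ratePre, s$ratePost, tolerance = 0.2)
  expect_equal(s$nDelayed, sum(ev >= 3.11 & ev < 4.11), tolerance = 1)
})

test_that("detector recall rises monotonically with signal-to-noise", {
  set.seed(77)
  truth <- sort(stats::runif(40, 0.05, 1.95))
  recall <- vapply(c(2, 5, 10, 20), function(snr) {
    tr <- synthesizeTrace(truth, wfDefault,
                          noiseSd = wfDefault@meanAmp / snr, dt = 2e-5,
                          seed = 100 + snr, duration = 2)
    ev <- detectEvents(tr)
    mean(vapply(truth, function(t0) any(abs(ev - t0) < 1.5e-3),
                logical(1)))
  }, numeric(1))
  expect_true(all(diff(recall) >= -0.025))
  expect_gt(recall[4], recall[1])
})
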