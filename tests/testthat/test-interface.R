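test_that("parameter configs round-trip through the TOML subset", {
  sets <- list(a = toyParams(), b = frozenParams())
  f1 <- tempfile(fileext = ".toml"); f2 <- tempfile(fileext = ".toml")
  writeParams(sets, f1)
  back <- readParams(f1)
  expect_equal(vesikit:::.paramsToList(back$a),
               vesikit:::.paramsToList(sets$a), tolerance = 1e-12)
  writeParams(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  one <- readParams(f1, "b")
  expect_equal(one@pFusion, sets$b@pFusion)
  expect_error(readParams(f1, "nope"), "no parameter table")
})

test_that("shipped defaults load and honour the resting pool calibration", {
  ps <- defaultParams()
  expect_named(ps, c("wt", "ko"))
  ssw <- restingSteadyState(ps$wt)
  expect_equal(as.numeric(ssw["ts"]), 656, tolerance = 1)
  expect_equal(as.numeric(ssw["ls"] + ssw["ts"]), 1749, tolerance = 2)
  ssk <- restingSteadyState(ps$ko)
  expect_equal(as.numeric(ssk["ts"]), 566, tolerance = 1)
  expect_equal(as.numeric(ssk["ls"] + ssk["ts"]), 1606, tolerance = 2)
  # resting spontaneous rates used for the basal fusion calibration
  rateW <- evalFusionLaw(ps$wt@tsLaw, 50) * ssw["ts"]
  expect_equal(as.numeric(rateW), 5.14, tolerance = 0.05)
})

test_that("protocols and tensors round-trip through CSV", {
  f <- tempfile(fileext = ".csv")
  utils::write.table(c(0.1, 0.2, 0.35), f, row.names = FALSE,
                     col.names = FALSE, sep = ",")
  pr <- readProtocol(f)
  expect_equal(pr@apTimes, c(0.1, 0.2, 0.35))

  m <- array(stats::runif(3 * 2 * 8, 0, 50), dim = c(3, 2, 8))
  tensor <- releaseTensor(m, c(10, 100))
  ft <- tempfile(fileext = ".csv")
  writeTensorCsv(tensor, ft)
  back <- readTensorCsv(ft)
  expect_equal(back@m, tensor@m, tolerance = 1e-12)
  expect_equal(back@freqs, tensor@freqs)
})

test_that("the resting-stage solver hits arbitrary pool targets exactly", {
  p <- toyParams()
  out <- solveRestingStage(p, tsRest = 200, docked = 420, spontRate = 1.5)
  ss <- restingSteadyState(out)
  expect_equal(as.numeric(ss["ts"]), 200, tolerance = 1e-4)
  expect_equal(as.numeric(ss["ls"] + ss["ts"]), 420, tolerance = 1e-4)
  expect_equal(as.numeric(evalFusionLaw(out@tsLaw, 50) * ss["ts"]), 1.5,
               tolerance = 1e-4)
})

test_that("calibration leaves a satisfied constraint set unchanged", {
  p <- toyParams()
  tsTarget <- as.numeric(restingSteadyState(p)["ts"])
  out <- calibrateModel(
    p, free = "k2_max",
    targets = list(list(
      name = "restTs",
      fn = function(q) as.numeric(restingSteadyState(q)["ts"]),
      target = tsTarget)),
    lower = c(k2_max = 0.05), upper = c(k2_max = 2), maxit = 50)
  expect_lt(out$rms, 1e-3)
  expect_equal(as.numeric(restingSteadyState(out$params)["ts"]), tsTarget,
               tolerance = 1e-3 * tsTarget)
})

test_that("the pipeline report is complete and reproducible", {
  p <- toyParams()
  spec <- populationSpec(nSynapses = 4, mtsRange = c(100, 400),
                         quantalNoiseCv = 0.05, freqs = c(10, 50, 100),
                         nAps = 15, seed = 3)
  r1 <- suppressWarnings(runPipeline(p, spec, s2Band = c(10, 50)))
  expect_true(all(c("initialPfusion", "slopePfusion", "s2Percent",
                    "depression1HzPercent", "frpCorrected", "seeds") %in%
                    names(r1)))
  r2 <- suppressWarnings(runPipeline(p, spec, s2Band = c(10, 50)))
  expect_identical(r1[names(r1) != "version"], r2[names(r2) != "version"])
  out <- tempfile(fileext = ".json")
  suppressWarnings(runPipeline(p, spec, s2Band = c(10, 50), out = out))
  expect_true(file.exists(out))
  parsed <- jsonlite::read_json(out)
  expect_equal(parsed$seeds$population, 3)
})
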