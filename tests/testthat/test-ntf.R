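test_that("a noise-free rank-2 tensor is recovered exactly", {
  fx <- makeRank2Tensor()
  fit <- ntfDecompose(fx$tensor, 2, seed = 0)
  normM <- sum(fx$tensor@m^2)
  expect_lt(fit@sse, 1e-10 * normM)
  # the split itself is recovered up to the small rotation freedom the
  # nonnegativity constraints leave open
  expect_lt(max(abs(as.numeric(fit@basefunctions[1, 1, ]) - fx$bf1)), 0.005)
  expect_lt(max(abs(as.numeric(fit@amplitudes[, 1]) / fx$a1 - 1)), 0.03)
})

test_that("scaling one synapse scales its amplitudes, not the shapes", {
  fx <- makeRank2Tensor(seed = 2)
  fit1 <- ntfDecompose(fx$tensor, 2, seed = 0)
  m2 <- fx$tensor@m
  m2[3, , ] <- 2 * m2[3, , ]
  fit2 <- ntfDecompose(releaseTensor(m2, fx$tensor@freqs), 2, seed = 0)
  expect_equal(as.numeric(fit2@amplitudes[3, 1] / fit1@amplitudes[3, 1]),
               2, tolerance = 1e-3)
  expect_equal(fit2@basefunctions[1, , ], fit1@basefunctions[1, , ],
               tolerance = 1e-3)
})

test_that("masked-out entries have no influence on the fit", {
  fx <- makeRank2Tensor(seed = 3)
  m <- fx$tensor@m
  mask <- array(TRUE, dim = dim(m))
  mask[2, 1, 5:10] <- FALSE
  t1 <- releaseTensor(m, fx$tensor@freqs, mask = mask)
  m[2, 1, 5:10] <- 1e6                      # absurd values behind the mask
  t2 <- releaseTensor(m, fx$tensor@freqs, mask = mask)
  f1 <- ntfDecompose(t1, 2, seed = 0)
  f2 <- ntfDecompose(t2, 2, seed = 0)
  expect_identical(f1@amplitudes, f2@amplitudes)
  expect_identical(f1@basefunctions, f2@basefunctions)
})

test_that("degenerate inputs are rejected", {
  z <- releaseTensor(array(0, dim = c(3, 2, 10)), c(10, 20))
  expect_error(ntfDecompose(z, 2), "all-zero")
  one <- releaseTensor(array(1, dim = c(1, 2, 10)), c(10, 20))
  expect_error(ntfDecompose(one, 2), "at least 2")
})

test_that("the initial TS basefunction value reads out the fusion probability", {
  nJ <- 30
  geo <- 0.3 * 0.7^(seq_len(nJ) - 1)
  bf <- array(0, dim = c(2, 4, nJ))
  for (f in 1:4) bf[1, f, ] <- geo / sum(geo)
  res <- new("NtfResult", amplitudes = matrix(1, 2, 2),
             basefunctions = bf, sse = 0, nIter = 1, converged = TRUE,
             freqs = c(5, 10, 20, 50))
  expect_equal(as.numeric(initialPfusion(res)), geo[1] / sum(geo),
               tolerance = 1e-12)
})

test_that("slope-based fusion probability estimation", {
  mts <- c(100, 300, 700, 1200)
  expect_equal(slopePfusion(0.4 * mts, mts), 0.4, tolerance = 1e-12)
  expect_error(slopePfusion(1, 2), "at least 2")
})

test_that("the conversion-fraction fit inverts its own recursion", {
  nJ <- 40
  r <- vesikit:::.recursionBf(0.2, 0.05, nJ)
  expect_equal(fitS2(r, 0.2), 0.05, tolerance = 1e-5)
  expect_equal(fitS2(rbind(r, r, r), 0.2), 0.05, tolerance = 1e-5)
  expect_error(fitS2(rep(0, nJ), 0.2), "degenerate")
})
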