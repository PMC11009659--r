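# build a tensor that satisfies the factorization conventions exactly:
# component 1 geometric (unit sum per frequency, tail-free), component 2
# anchored at zero on the first stimulus with negligible tail
makeRank2Tensor <- function(nI = 6, nF = 3, nJ = 25, p = 0.4, s2 = 0.3,
                            seed = 1) {
  set.seed(seed)
  geo <- p * (1 - p)^(seq_len(nJ) - 1)
  bf1 <- geo / sum(geo)
  L <- 1; T <- 0; r <- numeric(nJ)
  for (j in seq_len(nJ)) {
    r[j] <- p * T
    T <- T * (1 - p) + s2 * L
    L <- L * (1 - s2)
  }
  bf2 <- r / sum(r)
  a1 <- stats::runif(nI, 100, 1000)
  a2 <- stats::runif(nI, 100, 1000)
  m <- array(0, dim = c(nI, nF, nJ))
  for (f in seq_len(nF))
    m[, f, ] <- outer(a1, bf1) + outer(a2, bf2)
  list(tensor = releaseTensor(m, freqs = c(10, 20, 50)[seq_len(nF)]),
       a1 = a1, a2 = a2, bf1 = bf1, bf2 = bf2)
}
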