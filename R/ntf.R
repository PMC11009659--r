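# Nonnegative tensor factorization of release-train tensors.
#
# Model: m[i, f, j] ~ sum_c A[i, c] * B[c, f, j], with per-synapse
# amplitudes A shared across frequencies and basefunctions B shared across
# synapses. Depleting components (preexisting TS; preexisting LS in a
# three-component fit) carry per-frequency unit-sum basefunctions, so their
# amplitudes are the quanta contributed by the corresponding resting pool
# under the complete-depletion assumption.
#
# Two fitting regimes:
#  * two components: free-form HALS (hierarchical alternating least
#    squares) with nonnegativity clipping on the masked squared error,
#    pinned by two conventions: the non-TS component releases nothing on
#    the first stimulus, and the depleting component is tail-free (its
#    steady-state plateau is rotated into the replenishment component by an
#    exact reconstruction-preserving transfer).
#  * three components: a blind three-way split of 40-stimulus trains from
#    a dozen synapses is not identifiable (components can trade mass along
#    near-collinear amplitude directions at almost no cost), so the
#    basefunctions are constrained to parametric families implied by the
#    priming scheme: geometric depletion for TS, the loose-pool
#    conversion/depletion recursion for LS (per-frequency conversion
#    fraction, fusion probability shared with TS), and a saturating ramp
#    for replenishment. Amplitudes are profiled out by nonnegative least
#    squares per synapse.

.geoBf <- function(p, nJ) {
  g <- p * (1 - p)^(seq_len(nJ) - 1)
  g / sum(g)
}

.recursionBf <- function(p, s2, nJ) {
  L <- 1; T <- 0; r <- numeric(nJ)
  for (j in seq_len(nJ)) {
    r[j] <- p * T
    T <- T * (1 - p) + s2 * L
    L <- L * (1 - s2)
  }
  if (sum(r) > 0) r / sum(r) else r
}

.rampBf <- function(tau, nJ) {
  r <- 1 - exp(-(seq_len(nJ) - 1) / tau)
  r / r[nJ]                             # unit maximum: shape only
}

.ntfInitBf <- function(nComponents, nF, nJ, p0 = 0.3, seed = 0) {
  B <- array(0, dim = c(nComponents, nF, nJ))
  for (f in seq_len(nF)) B[1, f, ] <- .geoBf(p0, nJ)
  set.seed(seed)
  for (c in seq_len(nComponents)[-1]) {
    B[c, , ] <- matrix((1 + 1e-3 * stats::runif(nF * nJ)) / nJ, nF, nJ)
    B[c, , 1] <- 0                    # no first-stimulus release
  }
  B
}

# exact nonnegative least squares for a small number of columns by active
# set enumeration
.nnlsSmall <- function(X, y, w = NULL) {
  k <- ncol(X)
  if (!is.null(w)) { X <- X * sqrt(w); y <- y * sqrt(w) }
  best <- NULL; bestRss <- Inf
  for (mask in seq_len(2^k) - 1) {
    on <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    beta <- numeric(k)
    if (length(on)) {
      Xs <- X[, on, drop = FALSE]
      G <- crossprod(Xs)
      b <- try(solve(G, crossprod(Xs, y)), silent = TRUE)
      if (inherits(b, "try-error") || any(!is.finite(b)) || any(b < 0))
        next
      beta[on] <- b
    }
    rss <- sum((y - X %*% beta)^2)
    if (!is.finite(rss)) next
    if (rss < bestRss - 1e-12) { bestRss <- rss; best <- beta }
  }
  best
}

.ntfHals2 <- function(Y, M, nF, nJ, seed, maxIter, tol, normY) {
  nI <- nrow(Y); K <- nF * nJ
  nComponents <- 2
  Bm <- matrix(.ntfInitBf(2, nF, nJ, seed = seed), 2, K)
  G <- Bm %*% t(Bm)
  A <- t(solve(G + 1e-12 * diag(2), Bm %*% t(Y)))
  A[A < 0] <- 0
  fidx <- rep(seq_len(nF), times = nJ)
  jidx <- rep(seq_len(nJ), each = nF)
  sse <- Inf; it <- 0; converged <- FALSE
  repeat {
    it <- it + 1
    E <- (Y - A %*% Bm) * M
    for (c in 1:2) {
      Rc <- E + (A[, c] %o% Bm[c, ]) * M
      bc <- Bm[c, ]
      num <- as.numeric(Rc %*% bc)
      den <- as.numeric(M %*% (bc * bc))
      A[, c] <- ifelse(den > 0, pmax(num / den, 0), 0)
      num2 <- as.numeric(t(Rc) %*% A[, c])
      den2 <- as.numeric(t(M) %*% (A[, c]^2))
      Bm[c, ] <- ifelse(den2 > 0, pmax(num2 / den2, 0), 0)
      # only fusion-competent vesicles release on the first stimulus
      if (c > 1) Bm[c, jidx == 1] <- 0
      if (c == 1) {                     # per-frequency unit-sum projection
        s <- vapply(seq_len(nF),
                    function(f) sum(Bm[c, fidx == f]), numeric(1))
        sbar <- mean(s[s > 0])
        for (f in seq_len(nF)) if (s[f] > 0)
          Bm[c, fidx == f] <- Bm[c, fidx == f] / s[f]
        if (is.finite(sbar) && sbar > 0) A[, c] <- A[, c] * sbar
      }
      E <- Rc - (A[, c] %o% Bm[c, ]) * M
    }
    # tail-freeness: transfer the largest multiple of the replenishment
    # component contained in the depleting component's last five stimuli
    # (B1 <- B1 - a*B2, A2 <- A2 + a*A1 reconstructs identically)
    ok <- which(jidx > nJ - 5 & Bm[2, ] > 1e-9 * max(Bm[2, ]))
    if (length(ok)) {
      a <- max(0, min(Bm[1, ok] / Bm[2, ok]))
      if (a > 1e-6) {
        Bm[1, ] <- pmax(Bm[1, ] - a * Bm[2, ], 0)
        A[, 2] <- A[, 2] + a * A[, 1]
        s <- vapply(seq_len(nF),
                    function(f) sum(Bm[1, fidx == f]), numeric(1))
        sbar <- mean(s[s > 0])
        for (f in seq_len(nF)) if (s[f] > 0)
          Bm[1, fidx == f] <- Bm[1, fidx == f] / s[f]
        if (is.finite(sbar) && sbar > 0) A[, 1] <- A[, 1] * sbar
      }
    }
    E <- (Y - A %*% Bm) * M
    sseNew <- sum(E^2)
    if (is.finite(sse) &&
        abs(sse - sseNew) <= tol * max(sse, 1e-8 * normY)) {
      sse <- sseNew; converged <- TRUE; break
    }
    sse <- sseNew
    if (it >= maxIter) {
      warning("NTF did not reach the convergence tolerance")
      break
    }
  }
  list(A = A, Bm = Bm, sse = sse, it = it, converged = converged)
}

.ntfStructured3 <- function(Y, M, nF, nJ, maxIter) {
  nI <- nrow(Y)
  slices <- lapply(seq_len(nF), function(f) f + nF * (seq_len(nJ) - 1))
  bRow <- function(p, sig, tau, g) {
    B <- matrix(0, 3, nF * nJ)
    for (f in seq_len(nF)) {
      B[1, slices[[f]]] <- .geoBf(p, nJ)
      B[2, slices[[f]]] <- .recursionBf(p, sig[f], nJ)
      B[3, slices[[f]]] <- g[f] * .rampBf(tau[f], nJ)
    }
    B
  }
  profileA <- function(B) {
    A <- matrix(0, nI, 3)
    for (i in seq_len(nI)) {
      b <- .nnlsSmall(t(B), Y[i, ], w = M[i, ])
      if (!is.null(b)) A[i, ] <- b
    }
    A
  }
  sseOf <- function(B, A) sum(((Y - A %*% B) * M)^2)

  p <- 0.3; sig <- rep(0.05, nF); tau <- rep(5, nF); g <- rep(1, nF)
  B <- bRow(p, sig, tau, g)
  A <- profileA(B)
  sse <- sseOf(B, A); it <- 0; converged <- FALSE
  repeat {
    it <- it + 1
    # fusion probability: one-dimensional profile given everything else
    p <- stats::optimize(function(pp)
      sseOf(bRow(pp, sig, tau, g), A), c(0.02, 0.95), tol = 1e-6)$minimum
    # per-frequency loose-pool and replenishment shapes: the slices are
    # independent given p and the amplitudes; a short multi-start removes
    # the local optimum where the loose component degenerates to a ramp
    for (f in seq_len(nF)) {
      cols <- slices[[f]]
      yf <- Y[, cols]; mf <- M[, cols]
      geo <- .geoBf(p, nJ)
      sliceSse <- function(th) {
        b2 <- .recursionBf(p, stats::plogis(th[1]), nJ)
        b3 <- exp(th[3]) * .rampBf(exp(th[2]), nJ)
        fitMat <- A[, 1] %o% geo + A[, 2] %o% b2 + A[, 3] %o% b3
        sum(((yf - fitMat) * mf)^2)
      }
      best <- NULL
      for (s0 in unique(c(sig[f], 0.02, 0.08, 0.2))) {
        o <- stats::optim(c(stats::qlogis(s0), log(tau[f]),
                            log(max(g[f], 1e-6))), sliceSse,
                          method = "Nelder-Mead",
                          control = list(maxit = 400, reltol = 1e-12))
        if (is.null(best) || o$value < best$value) best <- o
      }
      sig[f] <- stats::plogis(best$par[1])
      tau[f] <- exp(best$par[2])
      g[f] <- exp(best$par[3])
    }
    gbar <- mean(g); g <- g / gbar      # scale lives in the amplitudes
    A[, 3] <- A[, 3] * gbar
    B <- bRow(p, sig, tau, g)
    A <- profileA(B)
    sseNew <- sseOf(B, A)
    if (abs(sse - sseNew) <= 1e-8 * max(sse, 1e-300)) {
      sse <- sseNew; converged <- TRUE; break
    }
    sse <- sseNew
    if (it >= max(30, maxIter / 100)) break
  }
  list(A = A, Bm = B, sse = sse, it = it, converged = converged)
}

#' Nonnegative tensor factorization of a release tensor
#'
#' Decomposes quantal release trains into per-synapse amplitudes and shared
#' basefunctions. With two components the first captures release of
#' vesicles residing in the fusion-competent tight state before
#' stimulation (geometric-like depletion, per-frequency unit sum, no
#' steady-state tail) and the second the remainder; the split is optimised
#' by masked HALS. With three components the second captures release fed
#' by the preexisting loose state and the third newly recruited vesicles;
#' because a free-form three-way split of this tensor is not identifiable,
#' the basefunctions are constrained to the parametric families implied by
#' the priming scheme (geometric depletion; loose-pool conversion
#' recursion; saturating replenishment ramp) and fitted by profiled
#' nonnegative least squares.
#'
#' @param tensor a [ReleaseTensor-class] with at least 2 synapses and 2
#'   frequencies
#' @param nComponents 2 or 3
#' @param seed integer seed for the (tiny, tie-breaking) initialisation
#'   jitter of the free-form fit
#' @param maxIter iteration cap
#' @param tol relative SSE change declaring convergence (two-component fit)
#' @return an [NtfResult-class]
#' @export
ntfDecompose <- function(tensor, nComponents = 2, seed = 0,
                         maxIter = 10000, tol = 1e-10) {
  stopifnot(nComponents %in% 2:3)
  d <- dim(tensor@m)
  if (d[1] < 2 || d[2] < 2)
    stop("need at least 2 synapses and 2 frequencies")
  nI <- d[1]; nF <- d[2]; nJ <- d[3]
  Y <- matrix(tensor@m, nI, nF * nJ)      # columns (f, j), f fastest
  M <- matrix(as.numeric(tensor@mask), nI, nF * nJ)
  Y <- Y * M
  if (all(Y == 0)) stop("degenerate input: all-zero tensor")
  fit <- if (nComponents == 2)
    .ntfHals2(Y, M, nF, nJ, seed, maxIter, tol, sum(Y^2))
  else
    .ntfStructured3(Y, M, nF, nJ, maxIter)
  Barr <- array(fit$Bm, dim = c(nComponents, nF, nJ))
  A <- fit$A
  rownames(A) <- tensor@synapseIds
  new("NtfResult", amplitudes = A, basefunctions = Barr, sse = fit$sse,
      nIter = fit$it, converged = fit$converged, freqs = tensor@freqs)
}

#' Initial fusion probability from the TS basefunction
#'
#' Under complete depletion the first element of the per-frequency
#' unit-sum TS basefunction equals the initial fusion probability; the
#' estimate is its average over frequencies. A warning flags dispersion
#' above 20% across frequencies.
#'
#' @param result an [NtfResult-class]
#' @return the fusion probability estimate, with the per-frequency values
#'   as attribute `perFrequency`
#' @export
initialPfusion <- function(result) {
  v <- result@basefunctions[1, , 1]
  est <- mean(v)
  if ((max(v) - min(v)) / est > 0.2)
    warning(sprintf(
      "initial BF_TS disperses by more than 20%% across frequencies (%.3g-%.3g)",
      min(v), max(v)))
  structure(est, perFrequency = v)
}

#' Fusion probability from the regression of m1 on the TS pool size
#'
#' Ordinary least-squares slope (free intercept) of the initial quantal
#' content against the NTF-derived resting TS pool across synapses: the
#' fraction of TS vesicles released by the first AP.
#'
#' @param m1 initial quantal contents, one per synapse
#' @param mts TS pool sizes, one per synapse
#' @return the regression slope
#' @export
slopePfusion <- function(m1, mts) {
  if (length(m1) != length(mts)) stop("m1 and mts disagree in length")
  if (length(m1) < 2) stop("underdetermined: need at least 2 synapses")
  as.numeric(stats::coef(stats::lm(m1 ~ mts))[2])
}

#' Per-interval loose-to-tight conversion fraction from the LS basefunction
#'
#' Fits the depletion/conversion recursion (with the fusion probability
#' held fixed) to the normalized timecourse of release fed by the
#' preexisting loose state: starting from L = 1, T = 0, each stimulus
#' releases p*T, then T <- T(1-p) + s2*L and L <- L(1-s2). The released
#' sequence, normalized to unit sum, is matched to BF_LS by least squares
#' over s2.
#'
#' @param bfLs numeric vector (one frequency) or matrix
#'   `[frequency, stimulus]` of LS basefunction values for the fitted band
#' @param pFusion fusion probability to constrain the fit, in (0, 1)
#' @return the fitted conversion fraction s2 in `[0, 1]`
#' @export
fitS2 <- function(bfLs, pFusion) {
  stopifnot(pFusion > 0, pFusion < 1)
  if (is.null(dim(bfLs))) bfLs <- matrix(bfLs, nrow = 1)
  if (all(bfLs <= 0)) stop("degenerate input: all-zero LS basefunction")
  nJ <- ncol(bfLs)
  obj <- function(s2) {
    r <- .recursionBf(pFusion, s2, nJ)
    sum((sweep(bfLs, 2, r)^2))
  }
  stats::optimize(obj, c(1e-6, 1 - 1e-6), tol = 1e-9)$minimum
}
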