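# Calibration driver and the end-to-end analysis pipeline.

#' Weighted least-squares calibration of free model parameters
#'
#' Minimises sum_k w_k * (f_k(params) - target_k)^2 over a named subset of
#' model parameters by bound-constrained derivative-free search
#' (Nelder-Mead on a logit-bounded reparameterisation). Constraint
#' functions receive the candidate parameter set and return one number
#' each; weights default to 1/target^2 (relative error) where the target
#' is nonzero.
#'
#' @param start a [ModelParams-class]
#' @param free character vector of flat parameter keys to optimise (the
#'   keys used in the TOML config, e.g. "k2_max", "s_ap", "bf",
#'   "ca_a_slow")
#' @param targets list of constraints, each
#'   `list(name =, fn = function(params) ..., target =, weight = NULL)`
#' @param lower,upper named bounds for the free parameters
#' @param maxit optimiser iteration budget
#' @param tol residual tolerance: a warning reports the worst constraints
#'   if the weighted RMS residual stays above it
#' @return list with `params` (calibrated set), `residuals` (data.frame
#'   name, value, target, relErr) and `rms`
#' @export
calibrateModel <- function(start, free, targets, lower, upper,
                           maxit = 200, tol = 0.05) {
  stopifnot(length(targets) >= 1, all(free %in% names(.paramsToList(start))),
            all(free %in% names(lower)), all(free %in% names(upper)))
  flat0 <- .paramsToList(start)
  toParams <- function(theta) {
    flat <- flat0
    vals <- lower[free] + (upper[free] - lower[free]) * stats::plogis(theta)
    flat[free] <- as.list(vals)
    # keep resting k2/k1 untouched; only listed keys move
    .paramsFromList(flat, label = start@label)
  }
  resid <- function(params) {
    vapply(targets, function(tg) {
      w <- if (!is.null(tg$weight)) tg$weight else
        if (tg$target != 0) 1 / tg$target^2 else 1
      sqrt(w) * (tg$fn(params) - tg$target)
    }, numeric(1))
  }
  obj <- function(theta) sum(resid(toParams(theta))^2)
  x0 <- stats::qlogis(pmin(pmax(
    (unlist(flat0[free]) - lower[free]) / (upper[free] - lower[free]),
    1e-3), 1 - 1e-3))
  opt <- if (length(free) == 1)
    stats::optim(x0, obj, method = "Brent", lower = -15, upper = 15,
                 control = list(maxit = maxit))
  else
    stats::optim(x0, obj, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-10))
  params <- toParams(opt$par)
  vals <- vapply(targets, function(tg) tg$fn(params), numeric(1))
  tgt <- vapply(targets, function(tg) tg$target, numeric(1))
  res <- data.frame(
    name = vapply(targets, function(tg) tg$name, character(1)),
    value = vals, target = tgt,
    relErr = ifelse(tgt != 0, (vals - tgt) / tgt, vals))
  rms <- sqrt(mean(resid(params)^2))
  if (rms > tol) {
    worst <- res[order(-abs(res$relErr)), ][1:min(3, nrow(res)), ]
    warning(sprintf(
      "calibration residual %.3g above tolerance; worst constraints: %s",
      rms, paste(sprintf("%s (%.3g vs %.3g)", worst$name, worst$value,
                         worst$target), collapse = ", ")))
  }
  list(params = params, residuals = res, rms = rms)
}

#' Analytic resting-state stage of the calibration
#'
#' Given the printed resting pool sizes and spontaneous release rates, the
#' resting balance of the scheme is linear and can be solved in closed
#' form: the resting k2 follows from the loose/tight ratio and the tight
#' pool's leak (b2 plus the spontaneous per-vesicle rate), b1 from the
#' requirement that the net docking influx equals the spontaneous outflow,
#' and the faulty-state occupancy from its own balance. This pins the
#' resting values exactly before any dynamic parameter is fitted.
#'
#' @param params a [ModelParams-class] supplying everything except the
#'   solved quantities
#' @param tsRest,docked resting tight pool and resting loose+tight sum
#'   (vesicle counts)
#' @param spontRate resting spontaneous release rate from the tight pool
#'   (1/s, sets the TS basal fusion rate)
#' @return the parameter set with ts basal, k2 rest and b1 replaced so the
#'   resting steady state matches the targets
#' @export
solveRestingStage <- function(params, tsRest, docked, spontRate) {
  lsRest <- docked - tsRest
  sigma <- spontRate / tsRest
  cR <- params@ca@cRest
  fsr <- evalFusionLaw(params@fsLaw, cR)
  kfR <- params@sk * params@priming1@kRest
  # FS and ES split the remaining sites according to the FS balance
  rest <- params@nTot - docked
  fsShare <- kfR / (params@bf + fsr)
  esRest <- rest / (1 + fsShare)
  fsRest <- rest - esRest
  k2R <- (params@b2 + sigma) * tsRest / lsRest
  b1 <- (params@priming1@kRest * esRest + params@b2 * tsRest) / lsRest - k2R
  if (b1 <= 0) stop("resting stage infeasible: nonpositive b1")
  flat <- .paramsToList(params)
  flat$ts_basal <- sigma
  flat$k2_rest <- k2R
  flat$b1 <- b1
  .paramsFromList(flat, label = params@label)
}

#' Run the full analysis pipeline for one genotype
#'
#' Generates a synthetic population from the parameter set, runs the
#' two- and three-component factorizations with the fusion-probability and
#' per-interval priming estimators, the 1 Hz steady-state depression, and
#' the train-based pool estimate, and returns a machine-readable report.
#'
#' @param params a [ModelParams-class]
#' @param spec a [PopulationSpec-class]
#' @param ntfSeed seed of the factorization initialisation
#' @param s2Band frequencies (Hz) entering the LS-basefunction fit
#' @param jitterSd per-synapse pool-composition jitter of the generator
#' @param out optional path: write the report as JSON
#' @return report list
#' @export
runPipeline <- function(params, spec = populationSpec(),
                        ntfSeed = 0, s2Band = c(5, 10, 20),
                        jitterSd = 0.7, out = NULL) {
  pop <- generatePopulation(spec, params, jitterSd = jitterSd)
  tensor <- pop$tensor
  ntf2 <- ntfDecompose(tensor, 2, seed = ntfSeed)
  pHat <- as.numeric(initialPfusion(ntf2))
  m1 <- rowMeans(tensor@m[, , 1])
  slope <- slopePfusion(m1, ntf2@amplitudes[, 1])
  ntf3 <- ntfDecompose(tensor, 3, seed = ntfSeed)
  bandIdx <- match(s2Band, tensor@freqs)
  bandIdx <- bandIdx[!is.na(bandIdx)]
  s2 <- fitS2(ntf3@basefunctions[2, bandIdx, ], pHat)
  sweep1 <- frequencySweep(params, 1, spec@nAps)
  frp <- frpFromModel(params)
  report <- list(
    genotype = params@label,
    seeds = list(population = spec@seed, ntf = ntfSeed),
    nSynapses = spec@nSynapses,
    initialPfusion = pHat,
    slopePfusion = slope,
    meanMts = mean(ntf2@amplitudes[, 1]),
    s2Percent = 100 * s2,
    depression1HzPercent = 100 * sweep1$depression,
    m1_1Hz = sweep1$m1, mss_1Hz = sweep1$mss,
    frpCorrected = frp$corrected,
    frpApparent = frp$apparent$frp,
    ntfSse = c(two = ntf2@sse, three = ntf3@sse),
    version = as.character(utils::packageVersion("vesikit")))
  if (!is.null(out))
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  report
}
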