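# Parameter-set serialisation. Calibrated wt/ko sets ship as a TOML config
# with one table per genotype; only the flat `[table] key = value` TOML
# subset is needed and a small reader/writer for exactly that subset lives
# here (no TOML package is declared as a dependency).

.tomlParse <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list(); current <- NULL
  for (ln in lines) {
    ln <- sub("#.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      current <- gsub("^\\[|\\]$", "", ln)
      out[[current]] <- list()
      next
    }
    kv <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(kv) != 3) stop("cannot parse config line: ", ln)
    key <- kv[2]; val <- trimws(kv[3])
    parsed <- if (grepl("^\\[.*\\]$", val)) {
      as.numeric(strsplit(gsub("^\\[|\\]$", "", val), ",")[[1]])
    } else if (grepl('^".*"$', val)) {
      gsub('^"|"$', "", val)
    } else if (val %in% c("true", "false")) {
      val == "true"
    } else {
      as.numeric(val)
    }
    if (is.null(current)) out[[key]] <- parsed else
      out[[current]][[key]] <- parsed
  }
  out
}

.tomlFormat <- function(x) {
  if (is.character(x)) sprintf('"%s"', x)
  else if (is.logical(x)) tolower(as.character(x))
  else if (length(x) > 1)
    sprintf("[%s]", paste(format(x, digits = 17, scientific = FALSE,
                                 trim = TRUE), collapse = ", "))
  else format(x, digits = 17, scientific = FALSE, trim = TRUE)
}

.tomlWrite <- function(tables, path, header = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(header)) writeLines(paste("#", header), con)
  for (tab in names(tables)) {
    writeLines(sprintf("[%s]", tab), con)
    vals <- tables[[tab]]
    for (key in names(vals))
      writeLines(sprintf("%s = %s", key, .tomlFormat(vals[[key]])), con)
    writeLines("", con)
  }
  invisible(path)
}

.paramsToList <- function(p) {
  list(n_tot = p@nTot,
       k1_rest = p@priming1@kRest, k1_max = p@priming1@kMax,
       k1_half = p@priming1@kHalf, b1 = p@b1,
       k2_rest = p@priming2@kRest, k2_max = p@priming2@kMax,
       k2_half = p@priming2@kHalf, b2 = p@b2,
       sk = p@sk, kf_max = p@primingF@kMax, kf_half = p@primingF@kHalf,
       bf = p@bf,
       p_fusion = p@pFusion, s_ap = p@sAp, k_untight = p@kUntight,
       ts_basal = p@tsLaw@basal, ts_gamma_max = p@tsLaw@gammaMax,
       ts_hill_n = p@tsLaw@hillN, ts_kd = p@tsLaw@kd,
       fs_basal = p@fsLaw@basal, fs_gamma_max = p@fsLaw@gammaMax,
       fs_hill_n = p@fsLaw@hillN, fs_kd = p@fsLaw@kd,
       ca_rest = p@ca@cRest, ca_a_fast = p@ca@aFast,
       ca_a_slow = p@ca@aSlow, ca_tau_fast = p@ca@tauFast,
       ca_tau_slow = p@ca@tauSlow)
}

.paramsFromList <- function(v, label = "") {
  ca <- calciumParams(v$ca_rest, v$ca_a_fast, v$ca_a_slow, v$ca_tau_fast,
                      v$ca_tau_slow)
  modelParams(
    nTot = v$n_tot,
    priming1 = primingLaw(v$k1_rest, v$k1_max, v$k1_half, c0 = v$ca_rest),
    b1 = v$b1,
    priming2 = primingLaw(v$k2_rest, v$k2_max, v$k2_half, c0 = v$ca_rest),
    b2 = v$b2, sk = v$sk, kfMax = v$kf_max, kfHalf = v$kf_half,
    bf = v$bf, pFusion = v$p_fusion, sAp = v$s_ap,
    kUntight = v$k_untight,
    tsLaw = fusionLaw(v$ts_basal, v$ts_gamma_max, v$ts_hill_n, v$ts_kd),
    fsLaw = fusionLaw(v$fs_basal, v$fs_gamma_max, v$fs_hill_n, v$fs_kd),
    ca = ca, label = label)
}

#' Read model parameter sets from a TOML config
#'
#' @param path config file with one `[genotype]` table per parameter set
#' @param genotype table to read; if NULL, all tables are returned as a
#'   named list
#' @return a [ModelParams-class] or named list of them
#' @export
readParams <- function(path, genotype = NULL) {
  tabs <- .tomlParse(path)
  tabs <- tabs[vapply(tabs, is.list, logical(1))]
  if (!is.null(genotype)) {
    if (is.null(tabs[[genotype]]))
      stop("no parameter table for genotype ", genotype)
    return(.paramsFromList(tabs[[genotype]], label = genotype))
  }
  lapply(stats::setNames(names(tabs), names(tabs)),
         function(g) .paramsFromList(tabs[[g]], label = g))
}

#' Write model parameter sets to a TOML config
#'
#' @param paramsList named list of [ModelParams-class] objects (names are
#'   table names)
#' @param path output file
#' @param header optional comment header
#' @return the path, invisibly
#' @export
writeParams <- function(paramsList, path, header = NULL) {
  .tomlWrite(lapply(paramsList, .paramsToList), path, header)
}

#' Calibrated default parameter sets
#'
#' Loads the parameter sets shipped with the package. These reproduce the
#' calyx-of-Held study conditions: wild-type and complexin-deficient
#' genotypes with resting pools, fusion probabilities, per-interval
#' priming, delayed-release kinetics and pool estimates as calibrated by
#' [calibrateModel()].
#'
#' @param genotype "wt" or "ko" (NULL for both)
#' @return a [ModelParams-class] or named list of them
#' @examples
#' wt <- defaultParams("wt")
#' restingSteadyState(wt)["ts"]
#' @export
defaultParams <- function(genotype = NULL) {
  readParams(system.file("extdata", "params.toml", package = "vesikit",
                         mustWork = TRUE), genotype)
}

#' Read a stimulus protocol from a CSV of AP times
#'
#' One AP time (seconds) per row, no header required.
#'
#' @param path CSV file
#' @param duration simulated time; defaults to last AP + 0.5 s
#' @return a [StimulusProtocol-class]
#' @export
readProtocol <- function(path, duration = NULL) {
  v <- utils::read.csv(path, header = FALSE)[[1]]
  stimulusProtocol(as.numeric(v), duration)
}

#' Write a release tensor as tidy CSV
#'
#' Columns: synapse_id, freq_hz, stim_index, m. Masked-out entries are
#' omitted.
#'
#' @param tensor a [ReleaseTensor-class]
#' @param path output file
#' @return the path, invisibly
#' @export
writeTensorCsv <- function(tensor, path) {
  d <- dim(tensor@m)
  df <- expand.grid(synapse = seq_len(d[1]), f = seq_len(d[2]),
                    j = seq_len(d[3]))
  df$m <- tensor@m[as.matrix(df)]
  df$keep <- tensor@mask[as.matrix(df[, 1:3])]
  out <- data.frame(synapse_id = tensor@synapseIds[df$synapse],
                    freq_hz = tensor@freqs[df$f], stim_index = df$j,
                    m = df$m)[df$keep, ]
  out <- out[order(out$synapse_id, out$freq_hz, out$stim_index), ]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a release tensor from tidy CSV
#'
#' @param path file written by [writeTensorCsv()] (columns synapse_id,
#'   freq_hz, stim_index, m); missing combinations become masked entries
#' @return a [ReleaseTensor-class]
#' @export
readTensorCsv <- function(path) {
  df <- utils::read.csv(path)
  ids <- sort(unique(df$synapse_id))
  freqs <- sort(unique(df$freq_hz))
  nJ <- max(df$stim_index)
  m <- array(NA_real_, dim = c(length(ids), length(freqs), nJ))
  idx <- cbind(match(df$synapse_id, ids), match(df$freq_hz, freqs),
               df$stim_index)
  m[idx] <- df$m
  releaseTensor(m, freqs, synapseIds = as.character(ids))
}
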