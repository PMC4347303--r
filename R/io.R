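# Persistence: a JSON trial-ensemble container (lossless round trip at
# native ms spike resolution, config snapshot and seeds embedded) and
# config-file loading.

#' Write a trial ensemble to a JSON container
#'
#' The container embeds a config snapshot, the seeds, per-trial spike times
#' and labels, and the common stimulus paths, so an ensemble round-trips
#' losslessly and the simulation is reproducible from the stored seeds.
#'
#' @param ensemble a \code{TrialEnsemble}.
#' @param path output file path.
#' @param storeTraces store common stimulus paths (needed for
#'   reverse-correlation analyses on the reloaded ensemble).
#' @return `path`, invisibly.
#' @export
writeEnsemble <- function(ensemble, path, storeTraces = TRUE) {
  stimCfg <- ensemble@stimConfig
  obj <- list(
    schema = "hierCP-ensemble",
    version = 1L,
    mode = ensemble@mode,
    preMs = ensemble@preMs, stimMs = ensemble@stimMs,
    recordFromMs = ensemble@recordFromMs, masterSeed = ensemble@masterSeed,
    stimConfig = list(I0 = stimCfg@I0, coherence = stimCfg@coherence,
      gamma = stimCfg@gamma, sigma = stimCfg@sigma, tauStim = stimCfg@tauStim,
      durationMs = stimCfg@durationMs, replicate = stimCfg@replicate),
    populations = ensemble@populations,
    labels = as.data.frame(ensemble@labels),
    trials = lapply(ensemble@trials, function(tr)
      list(sensId = tr$sensId, sensT = tr$sensT,
           intId = tr$intId, intT = tr$intT)),
    traces = if (storeTraces) lapply(ensemble@stimTraces, function(tr)
      list(id = tr@id, stimSeed = tr@stimSeed, zE1 = tr@zE1, zE2 = tr@zE2))
      else list()
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a trial ensemble from a JSON container
#'
#' @param path container path written by \code{\link{writeEnsemble}}.
#' @return A \code{TrialEnsemble}.
#' @export
readEnsemble <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE, simplifyMatrix = FALSE)
  if (is.null(obj$schema) || obj$schema != "hierCP-ensemble")
    stop("not a hierCP ensemble container")
  if (obj$version > 1) stop("container schema version ", obj$version,
                            " is newer than this reader")
  sc <- obj$stimConfig
  stimCfg <- new("StimulusConfig", I0 = sc$I0, coherence = sc$coherence,
    gamma = sc$gamma, sigma = sc$sigma, tauStim = sc$tauStim,
    durationMs = sc$durationMs, replicate = sc$replicate)
  asTrial <- function(tr) list(
    sensId = as.integer(unlist(tr$sensId)), sensT = as.numeric(unlist(tr$sensT)),
    intId = as.integer(unlist(tr$intId)), intT = as.numeric(unlist(tr$intT)))
  trials <- if (is.data.frame(obj$trials))
    lapply(seq_len(nrow(obj$trials)), function(i) asTrial(obj$trials[i, ]))
  else lapply(obj$trials, asTrial)
  asTrace <- function(tr)
    new("StimulusTrace", config = stimCfg, id = as.integer(tr$id),
        stimSeed = as.numeric(tr$stimSeed),
        zE1 = as.numeric(unlist(tr$zE1)), zE2 = as.numeric(unlist(tr$zE2)))
  traces <- if (is.data.frame(obj$traces))
    lapply(seq_len(nrow(obj$traces)), function(i) asTrace(obj$traces[i, ]))
  else lapply(obj$traces, asTrace)
  lab <- obj$labels
  new("TrialEnsemble", trials = trials, labels = DataFrame(lab),
      mode = obj$mode, populations = as.data.frame(obj$populations),
      stimConfig = stimCfg, stimTraces = traces, preMs = obj$preMs,
      stimMs = obj$stimMs, recordFromMs = obj$recordFromMs,
      masterSeed = obj$masterSeed)
}

#' Load a network/stimulus configuration file
#'
#' YAML configuration with top-level sections `network` (bFB,
#' backgroundMode, scale, gFF and overrides of the parameter tree) and
#' `stimulus` (arguments of \code{\link{stimulusConfig}}). Unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return List with validated `network` (\code{NetworkConfig}) and
#'   `stimulus` (\code{StimulusConfig}).
#' @export
#' @examples
#' cfg <- loadConfig(system.file("extdata", "example-config.yaml",
#'                               package = "hierCP"))
#' cfg$network
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  bad <- setdiff(names(y), c("network", "stimulus"))
  if (length(bad)) stop("unknown config sections: ", paste(bad, collapse = ", "))
  nw <- y$network %||% list()
  badN <- setdiff(names(nw), c("bFB", "backgroundMode", "scale", "gFF", "params"))
  if (length(badN)) stop("unknown network keys: ", paste(badN, collapse = ", "))
  params <- defaultParameters()
  if (!is.null(nw$params)) params <- modifyList(params, nw$params)
  netCfg <- networkConfig(bFB = nw$bFB %||% 0,
    backgroundMode = nw$backgroundMode %||% "global",
    scale = nw$scale %||% 1, gFF = nw$gFF, params = params)
  st <- y$stimulus %||% list()
  badS <- setdiff(names(st), c("coherence", "sigma", "gamma", "I0", "tauStim",
                               "durationMs", "replicate"))
  if (length(badS)) stop("unknown stimulus keys: ", paste(badS, collapse = ", "))
  stimCfg <- do.call(stimulusConfig, st)
  list(network = netCfg, stimulus = stimCfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
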