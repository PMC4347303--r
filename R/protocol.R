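# Trial protocol: fixed-duration trials (3 s pre-stimulus + 2 s stimulus by
# default), choice read out from the decision populations, batches with
# per-trial derived seeds.

# smoothed population rate (sp/s) at 1 ms centres over [0, toMs) trial time
# from spike times of `n` neurons; box kernel of width T (window half-open
# (t-T/2, t+T/2])
rateTrace <- function(times, n, toMs, T = 50) {
  nb <- as.integer(toMs)
  counts <- tabulate(pmin(nb, floor(times) + 1L), nbins = nb)
  cs <- c(0, cumsum(counts))
  centres <- seq_len(nb) - 0.5
  lo <- pmax(0, floor(centres - T / 2))
  hi <- pmin(nb, floor(centres + T / 2))
  w <- (hi - lo) / 1000
  (cs[hi + 1L] - cs[lo + 1L]) / (n * w)
}

#' Read the network's choice from a trial
#'
#' The choice is the decision population (D1 or D2) with the higher
#' population firing rate over the last `window` ms of the stimulus period;
#' an exact tie is broken by a seeded fair coin so that it is reproducible.
#'
#' @param trial a trial element (list with `intId`, `intT`).
#' @param nD1,nD2 decision population sizes (ids 0..nD1-1 are D1).
#' @param stimEndMs trial time of stimulus offset, ms.
#' @param window readout window, ms.
#' @param tieSeed seed for the tie-breaking coin.
#' @return Choice, 1 or 2.
#' @export
readChoice <- function(trial, nD1, nD2, stimEndMs, window = 50, tieSeed = 1) {
  sel <- trial$intT > stimEndMs - window & trial$intT <= stimEndMs
  ids <- trial$intId[sel]
  r1 <- sum(ids < nD1) / nD1
  r2 <- sum(ids >= nD1 & ids < nD1 + nD2) / nD2
  if (r1 == r2)
    return(if (withSeed(deriveSeed(tieSeed, "choice-tie"), runif(1)) < 0.5) 1L else 2L)
  if (r1 > r2) 1L else 2L
}

#' Run a single trial
#'
#' Simulates `preMs` of spontaneous activity (to wash out initial
#' conditions) followed by the stimulus epoch with injected stimulus
#' currents. Background spike trains are freshly drawn from `bgSeed`;
#' initial membrane potentials are uniform in [reset, threshold) from
#' `initSeed`. The result is a pure function of (network, stimulus, seeds).
#'
#' @param network a \code{Network}.
#' @param stimulus a \code{StimulusTrace}.
#' @param preMs pre-stimulus interval, ms.
#' @param bgSeed,initSeed integer seeds.
#' @param recordFromMs discard spikes before this trial time (ms).
#' @param recordPops character vector of populations to record.
#' @param voltageIds 0-based sensory ids whose membrane potential is
#'   recorded at 1 ms resolution (testing/diagnostics).
#' @return A list: `sensId`, `sensT`, `intId`, `intT` (spikes), `choice`,
#'   `stimulusId`, `stimSeed`, `coherence`, `vTrace`.
#' @export
runTrial <- function(network, stimulus, preMs = 3000, bgSeed = 1, initSeed = 1,
                     recordFromMs = NULL, recordPops = c("E1", "E2", "D1", "D2"),
                     voltageIds = integer(0)) {
  a <- network@arrays
  stimMs <- stimulus@config@durationMs
  if (is.null(recordFromMs)) recordFromMs <- max(0, preMs - 500)
  pops <- network@populations
  sensPop <- pops$population[pops$circuit == "sensory"]
  intPop <- pops$population[pops$circuit == "integration"]
  run <- list(dt = network@config@params$common$dtMs, preMs = preMs,
    stimMs = stimMs,
    delaySteps = as.integer(round(network@config@params$common$delayMs /
                                  network@config@params$common$dtMs)),
    bgSeed = bgSeed, initSeed = initSeed, recordFromMs = recordFromMs,
    recordSensory = sensPop %in% recordPops,
    recordIntegration = intPop %in% recordPops,
    voltageIds = as.integer(voltageIds))
  st <- stimArrays(stimulus, network)
  res <- .simulateTrialCpp(a, st, run)
  sz <- populationSizes(network@config)
  choice <- readChoice(res, sz$nD1, sz$nD2, preMs + stimMs,
                       tieSeed = bgSeed)
  list(sensId = res$sensId, sensT = res$sensT,
       intId = res$intId, intT = res$intT,
       choice = choice, stimulusId = stimulus@id,
       stimSeed = stimulus@stimSeed,
       coherence = stimulus@config@coherence,
       vTrace = res$vTrace)
}

#' Run a batch of trials
#'
#' Runs `nTrials` trials of the same realized network (same connectivity)
#' with per-trial derived seeds for background inputs, initial conditions
#' and (in non-replicate mode) the stimulus realization. In replicate mode a
#' bank of `nStimuli` frozen stimuli is generated and presented cyclically,
#' so each bank entry is replayed bit-identically across its trials.
#'
#' @param network a \code{Network}.
#' @param stimConfig a \code{StimulusConfig} (its `replicate` flag is
#'   overridden by `mode`).
#' @param nTrials number of trials.
#' @param mode "non-replicate" (fresh stimulus per trial) or "replicate".
#' @param masterSeed master seed; the ensemble is a pure function of it.
#' @param nStimuli bank size in replicate mode.
#' @param preMs pre-stimulus interval, ms.
#' @param recordFromMs recording start (default 500 ms before onset).
#' @param progress print per-trial progress.
#' @return A \code{TrialEnsemble}.
#' @export
runBatch <- function(network, stimConfig, nTrials, mode = c("non-replicate", "replicate"),
                     masterSeed = 1, nStimuli = 100, preMs = 3000,
                     recordFromMs = NULL, progress = FALSE) {
  mode <- match.arg(mode)
  stopifnot(nTrials >= 1)
  if (is.null(recordFromMs)) recordFromMs <- max(0, preMs - 500)
  if (mode == "replicate") {
    bank <- replicateBank(stimConfig, nStimuli, deriveSeed(masterSeed, "bank"))
    stimIdx <- ((seq_len(nTrials) - 1L) %% nStimuli) + 1L
  } else {
    bank <- NULL
    stimIdx <- seq_len(nTrials)
  }
  trials <- vector("list", nTrials)
  lab <- data.frame(choice = integer(nTrials), coherence = numeric(nTrials),
    stimulusId = integer(nTrials), stimSeed = numeric(nTrials),
    bgSeed = numeric(nTrials), initSeed = numeric(nTrials))
  traces <- if (mode == "replicate") bank else vector("list", nTrials)
  for (i in seq_len(nTrials)) {
    stimTr <- if (mode == "replicate") bank[[stimIdx[i]]]
      else makeStimulus(stimConfig, deriveSeed(masterSeed, "trial-stim", i), id = i)
    bgSeed <- deriveSeed(masterSeed, "trial-bg", i)
    initSeed <- deriveSeed(masterSeed, "trial-init", i)
    tr <- runTrial(network, stimTr, preMs = preMs, bgSeed = bgSeed,
                   initSeed = initSeed, recordFromMs = recordFromMs)
    trials[[i]] <- tr[c("sensId", "sensT", "intId", "intT")]
    lab$choice[i] <- tr$choice
    lab$coherence[i] <- tr$coherence
    lab$stimulusId[i] <- tr$stimulusId
    lab$stimSeed[i] <- tr$stimSeed
    lab$bgSeed[i] <- bgSeed
    lab$initSeed[i] <- initSeed
    if (mode == "non-replicate") traces[[i]] <- stimTr
    if (progress) message(sprintf("trial %d/%d: choice %d", i, nTrials, tr$choice))
  }
  new("TrialEnsemble", trials = trials, labels = DataFrame(lab), mode = mode,
      populations = network@populations, stimConfig = stimConfig,
      stimTraces = traces, preMs = preMs, stimMs = stimConfig@durationMs,
      recordFromMs = recordFromMs, masterSeed = masterSeed)
}

#' Number of trials in an ensemble
#' @param ensemble a \code{TrialEnsemble}.
#' @return Integer.
#' @export
nTrials <- function(ensemble) length(ensemble@trials)

#' Per-trial labels
#' @param ensemble a \code{TrialEnsemble}.
#' @return DataFrame of per-trial labels.
#' @export
trialLabels <- function(ensemble) ensemble@labels

#' Exclude replicate stimuli with overly consistent choices
#'
#' A bank stimulus is excluded iff more than 95% of its trials end in the
#' same choice (strict inequality), because too few trials of the minority
#' choice remain to estimate choice probability.
#'
#' @param ensemble a replicate-mode \code{TrialEnsemble}.
#' @param maxFraction consistency bound (default 0.95).
#' @return List with `kept`, `excluded` (stimulus ids) and the per-stimulus
#'   choice-1 fraction table.
#' @export
filterReplicateStimuli <- function(ensemble, maxFraction = 0.95) {
  if (ensemble@mode != "replicate")
    stop("replicate-stimulus filtering requires a replicate ensemble")
  lab <- as.data.frame(ensemble@labels)
  tab <- do.call(rbind, lapply(split(lab, lab$stimulusId), function(d)
    data.frame(stimulusId = d$stimulusId[1], nTrials = nrow(d),
               frac1 = mean(d$choice == 1))))
  consistent <- pmax(tab$frac1, 1 - tab$frac1)
  list(kept = tab$stimulusId[consistent <= maxFraction],
       excluded = tab$stimulusId[consistent > maxFraction],
       table = tab)
}

#' Make the network heterogeneous in stimulus and feedback inputs
#'
#' Randomly splits each sensory excitatory population into four equal groups
#' receiving (1) both stimulus modulations and top-down feedback (S+FB+),
#' (2) only stimulus (S+FB-), (3) only top-down (S-FB+), (4) neither
#' (S-FB-). Compensations keep the per-neuron input-current s.d. and the
#' population-mean top-down drive equal to the homogeneous network: S+
#' neurons get sigma_stim,k = sqrt(2) x 0.212 sigma with sigma_ind,k = 0 and
#' S- the converse; FB+ neurons get b_FB,k = 2 b_FB.
#'
#' @param config a homogeneous \code{NetworkConfig} (population sizes must
#'   be divisible by 4).
#' @param seed seed for the random group split.
#' @return The modified config; its `heterogeneity` slot holds the map
#'   (group, bFBfac, sigStimFac, sigIndFac per sensory neuron).
#' @export
makeHeterogeneous <- function(config, seed = 1) {
  if (!is.null(config@heterogeneity)) stop("config is already heterogeneous")
  sz <- populationSizes(config)
  if (sz$nE1 %% 4 != 0 || sz$nE2 %% 4 != 0)
    stop("population size not divisible by 4")
  Ns <- sz$nE1 + sz$nE2 + sz$nIs
  groups <- c("S+FB+", "S+FB-", "S-FB+", "S-FB-")
  assign1 <- function(n, idx) {
    g <- rep(groups, each = n / 4)
    sample(g)
  }
  withSeed(deriveSeed(seed, "heterogeneity"), {
    g <- c(assign1(sz$nE1), assign1(sz$nE2), rep(NA_character_, sz$nIs))
  })
  sPlus <- !is.na(g) & g %in% c("S+FB+", "S+FB-")
  fbPlus <- !is.na(g) & g %in% c("S+FB+", "S-FB+")
  het <- list(group = g,
    bFBfac = ifelse(fbPlus, 2, 0),
    sigStimFac = ifelse(sPlus, sqrt(2), 0),
    sigIndFac = ifelse(sPlus, 0, sqrt(2)))
  het$bFBfac[is.na(g)] <- 1
  het$sigStimFac[is.na(g)] <- 1
  het$sigIndFac[is.na(g)] <- 1
  config@heterogeneity <- het
  config
}

#' Classify trials by non-absorbing bound crossings
#'
#' For each trial, the smoothed population rates of D1 and D2 (box kernel of
#' width T) are scanned during the stimulus for the first crossing of the
#' bound theta. A trial is a reversal if the final choice population differs
#' from the first-crossing population, consistent if they agree, and
#' no-crossing if neither population reaches theta. Confidence is the rate
#' difference (chosen minus unchosen) averaged over the second half of the
#' stimulus.
#'
#' @param ensemble a \code{TrialEnsemble} with D1/D2 spikes recorded.
#' @param theta bound, sp/s (must exceed the spontaneous decision rate).
#' @param T rate smoothing window, ms.
#' @return A \code{BoundAnalysis}.
#' @export
classifyBoundTrials <- function(ensemble, theta, T = 50) {
  pops <- ensemble@populations
  nD1 <- sum(pops$population == "D1")
  nD2 <- sum(pops$population == "D2")
  on <- ensemble@preMs; off <- on + ensemble@stimMs
  half <- on + ensemble@stimMs / 2
  lab <- as.data.frame(ensemble@labels)
  n <- nTrials(ensemble)
  cls <- character(n); fct <- rep(NA_real_, n); fcp <- rep(NA_integer_, n)
  conf <- numeric(n)
  for (i in seq_len(n)) {
    tr <- ensemble@trials[[i]]
    d1 <- tr$intT[tr$intId < nD1]
    d2 <- tr$intT[tr$intId >= nD1 & tr$intId < nD1 + nD2]
    r1 <- rateTrace(d1, nD1, off, T)
    r2 <- rateTrace(d2, nD2, off, T)
    idx <- seq_len(as.integer(off))
    inStim <- idx > on
    c1 <- which(inStim & r1 >= theta)[1]
    c2 <- which(inStim & r2 >= theta)[1]
    lateIdx <- idx > half & idx <= off
    dMean <- mean(r1[lateIdx]) - mean(r2[lateIdx])
    conf[i] <- if (lab$choice[i] == 1) dMean else -dMean
    if (is.na(c1) && is.na(c2)) {
      cls[i] <- "no-crossing"
    } else {
      firstPop <- if (is.na(c2) || (!is.na(c1) && c1 <= c2)) 1L else 2L
      fcp[i] <- firstPop
      fct[i] <- (if (firstPop == 1L) c1 else c2) - on
      cls[i] <- if (firstPop == lab$choice[i]) "consistent" else "reversal"
    }
  }
  new("BoundAnalysis",
      table = DataFrame(class = cls, firstCrossMs = fct,
                        firstCrossPop = fcp, confidence = conf),
      theta = theta, T = T)
}
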