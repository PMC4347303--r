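# Choice probability: ROC-area time courses per neuron, unit selection,
# population averages and the across-neuron CP stability matrix.

#' ROC area (choice probability) from two count samples
#'
#' Area under the ROC curve classifying preferred-choice versus
#' non-preferred-choice spike counts; equals the normalized Mann-Whitney
#' statistic (pairs with pref > null, plus half credit for ties, divided by
#' the number of pairs). 0.5 is chance.
#'
#' @param pref,null numeric spike-count vectors.
#' @return CP in [0, 1].
#' @export
#' @examples
#' rocArea(c(2, 3), c(1, 2)) # 0.875
rocArea <- function(pref, null) {
  n1 <- length(pref); n2 <- length(null)
  if (n1 == 0 || n2 == 0) return(NA_real_)
  r <- rank(c(pref, null))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# preferred choice of sensory neurons: structural population identity
preferredChoice <- function(ensemble, neurons) {
  sens <- ensemble@populations[ensemble@populations$circuit == "sensory", ]
  pop <- sens$population[match(neurons, sens$id)]
  ifelse(pop == "E1", 1L, ifelse(pop == "E2", 2L, NA_integer_))
}

#' Choice-probability time course per neuron
#'
#' CP_k(t; T) per bin from the ROC of the choice-split spike counts. The
#' preferred choice of model neurons is structural (choice 1 for E1,
#' choice 2 for E2). By default the analysis is restricted to
#' zero-coherence trials. Bins (neurons) with fewer than 5 trials in either
#' choice class are masked.
#'
#' @param ensemble a \code{TrialEnsemble}.
#' @param neurons 0-based sensory E neuron ids.
#' @param T count window, ms.
#' @param binCenters bin centres, ms from onset; default a sliding grid
#'   every 50 ms over the stimulus.
#' @param mode "fixed" or "adjusted" count windows.
#' @param zeroCoherenceOnly restrict to c = 0 trials.
#' @param minPerClass minimum trials per choice class.
#' @return A \code{CPTimeCourse}.
#' @export
cpTimecourse <- function(ensemble, neurons, T = 100, binCenters = NULL,
                         mode = c("fixed", "adjusted"),
                         zeroCoherenceOnly = TRUE, minPerClass = 5) {
  mode <- match.arg(mode)
  if (is.null(binCenters))
    binCenters <- seq(T / 2, ensemble@stimMs - T / 2, by = 50)
  lab <- as.data.frame(ensemble@labels)
  trials <- seq_len(nTrials(ensemble))
  if (zeroCoherenceOnly) trials <- trials[lab$coherence == 0]
  ch <- lab$choice[trials]
  cm <- spikeCounts(ensemble, neurons, T = T, binCenters = binCenters,
                    mode = mode, trials = trials)
  pref <- preferredChoice(ensemble, neurons)
  nn <- length(neurons); nb <- length(binCenters)
  cp <- matrix(NA_real_, nn, nb)
  nPref <- integer(nn); nNull <- integer(nn)
  for (k in seq_len(nn)) {
    isPref <- ch == pref[k]
    nPref[k] <- sum(isPref); nNull[k] <- sum(!isPref)
    if (nPref[k] < minPerClass || nNull[k] < minPerClass) next
    for (b in seq_len(nb))
      cp[k, b] <- rocArea(cm@counts[k, isPref, b], cm@counts[k, !isPref, b])
  }
  new("CPTimeCourse", cp = cp, binCenters = binCenters, T = T, mode = mode,
      neuronIds = as.integer(neurons), preferred = pref,
      nPref = nPref, nNull = nNull)
}

#' Apply unit-selection criteria
#'
#' The selection rules used for choice-probability analyses, applied in
#' order after per-neuron outlier-trial removal (trials whose full-stimulus
#' spike count deviates from the neuron's mean by more than `outlierSd`
#' standard deviations): (1) strictly more than `minTrials` zero-coherence
#' trials, (2) at least `minPerChoice` preferred and non-preferred choices,
#' (3) average firing rate above `minRate`, (4) at least `minSpikes` spikes
#' across all trials.
#'
#' @param ensemble a \code{TrialEnsemble}.
#' @param neurons candidate 0-based sensory E ids (default all E neurons).
#' @param minTrials,minPerChoice,minRate,minSpikes,outlierSd rule
#'   parameters.
#' @return List: `included` ids, `excludedBy` per-rule counts,
#'   `outlierTrials` per-neuron excluded trial indices.
#' @export
selectUnits <- function(ensemble, neurons = NULL, minTrials = 20,
                        minPerChoice = 5, minRate = 1, minSpikes = 100,
                        outlierSd = 3) {
  pops <- ensemble@populations
  if (is.null(neurons))
    neurons <- pops$id[pops$circuit == "sensory" & pops$population %in% c("E1", "E2")]
  lab <- as.data.frame(ensemble@labels)
  zeroTrials <- which(lab$coherence == 0)
  cm <- spikeCounts(ensemble, neurons, T = ensemble@stimMs,
                    binCenters = ensemble@stimMs / 2, trials = zeroTrials)
  pref <- preferredChoice(ensemble, neurons)
  excludedBy <- c(outliers = 0L, trials = 0L, choices = 0L, rate = 0L, spikes = 0L)
  included <- logical(length(neurons))
  outlierTrials <- vector("list", length(neurons))
  for (k in seq_along(neurons)) {
    n <- cm@counts[k, , 1]
    keep <- rep(TRUE, length(n))
    if (sd(n) > 0) keep <- abs(n - mean(n)) <= outlierSd * sd(n)
    outlierTrials[[k]] <- zeroTrials[!keep]
    excludedBy["outliers"] <- excludedBy["outliers"] + sum(!keep)
    nk <- n[keep]; chk <- lab$choice[zeroTrials][keep]
    if (length(nk) <= minTrials) { excludedBy["trials"] <- excludedBy["trials"] + 1L; next }
    if (sum(chk == pref[k]) < minPerChoice || sum(chk != pref[k]) < minPerChoice) {
      excludedBy["choices"] <- excludedBy["choices"] + 1L; next
    }
    if (mean(nk) / ensemble@stimMs * 1000 <= minRate) {
      excludedBy["rate"] <- excludedBy["rate"] + 1L; next
    }
    if (sum(nk) < minSpikes) { excludedBy["spikes"] <- excludedBy["spikes"] + 1L; next }
    included[k] <- TRUE
  }
  list(included = neurons[included], excludedBy = excludedBy,
       outlierTrials = outlierTrials)
}

#' Population-averaged CP time course
#'
#' Averages CP_k(t; T) over a seeded random sample of excitatory sensory
#' neurons with a minimum firing rate, reporting the mean and s.e.m. across
#' neurons per bin.
#'
#' @param ensemble a \code{TrialEnsemble}.
#' @param nNeurons sample size (all eligible neurons, with a warning, if
#'   fewer are available).
#' @param minRate eligibility threshold, sp/s over the stimulus.
#' @param seed sampling seed.
#' @param T count window, ms.
#' @param binCenters bin centres (default sliding grid every 50 ms).
#' @param mode fixed or adjusted windows.
#' @return List: `binCenters`, `mean`, `sem`, `neurons`, `cp` (the
#'   underlying \code{CPTimeCourse}).
#' @export
populationCP <- function(ensemble, nNeurons = 100, minRate = 1, seed = 1,
                         T = 100, binCenters = NULL, mode = "fixed") {
  pops <- ensemble@populations
  eIds <- pops$id[pops$circuit == "sensory" & pops$population %in% c("E1", "E2")]
  lab <- as.data.frame(ensemble@labels)
  zeroTrials <- which(lab$coherence == 0)
  cmAll <- spikeCounts(ensemble, eIds, T = ensemble@stimMs,
                       binCenters = ensemble@stimMs / 2, trials = zeroTrials)
  rates <- apply(cmAll@counts[, , 1, drop = FALSE], 1, mean) / ensemble@stimMs * 1000
  eligible <- eIds[rates >= minRate]
  if (length(eligible) < nNeurons) {
    warning(sprintf("only %d eligible neurons; using all", length(eligible)))
    sel <- eligible
  } else {
    sel <- withSeed(deriveSeed(seed, "population-cp"),
                    sort(sample(eligible, nNeurons)))
  }
  ct <- cpTimecourse(ensemble, sel, T = T, binCenters = binCenters, mode = mode)
  mu <- colMeans(ct@cp, na.rm = TRUE)
  sem <- apply(ct@cp, 2, function(x) sd(x, na.rm = TRUE) / sqrt(sum(is.finite(x))))
  list(binCenters = ct@binCenters, mean = mu, sem = sem, neurons = sel, cp = ct)
}

#' Across-neuron CP stability (CP correlation) matrix
#'
#' For each of `nResamples` random trial subsamples of size `nTrialsSub`,
#' per-neuron CP is computed at the 8 non-overlapping bins (T = 250 ms) and
#' the Spearman rank correlation across neurons is taken for every bin
#' pair; the resample mean and s.e. are reported, together with the
#' adjacent-bin series C(t_i, t_{i+1}), its least-squares slope against
#' time and a permutation p-value for the slope.
#'
#' @param ensemble a \code{TrialEnsemble}.
#' @param neurons 0-based sensory E ids.
#' @param T window, ms (8 bins must fit in the stimulus).
#' @param nTrialsSub trials per resample (error if more than available).
#' @param nResamples number of resamples.
#' @param seed resampling seed.
#' @param nPerm permutations for the slope test.
#' @return A \code{CPCorrelationMatrix}.
#' @export
cpCorrelationMatrix <- function(ensemble, neurons, T = 250, nTrialsSub = 100,
                                nResamples = 1000, seed = 1, nPerm = 1000) {
  lab <- as.data.frame(ensemble@labels)
  zeroTrials <- which(lab$coherence == 0)
  if (nTrialsSub > length(zeroTrials))
    stop("nTrialsSub exceeds the available zero-coherence trials")
  nb <- 8L
  binCenters <- (seq_len(nb) - 0.5) * T
  if (max(binCenters) + T / 2 > ensemble@stimMs)
    stop("stimulus epoch shorter than 8 bins")
  cm <- spikeCounts(ensemble, neurons, T = T, binCenters = binCenters,
                    trials = zeroTrials)
  pref <- preferredChoice(ensemble, neurons)
  ch <- lab$choice[zeroTrials]
  nn <- length(neurons)
  acc <- array(0, c(nb, nb)); acc2 <- array(0, c(nb, nb))
  withSeed(deriveSeed(seed, "cp-matrix"), {
    for (r in seq_len(nResamples)) {
      sub <- sample(length(zeroTrials), nTrialsSub)
      cp <- matrix(NA_real_, nn, nb)
      for (k in seq_len(nn)) {
        isPref <- ch[sub] == pref[k]
        if (sum(isPref) < 2 || sum(!isPref) < 2) next
        for (b in seq_len(nb))
          cp[k, b] <- rocArea(cm@counts[k, sub[isPref], b],
                              cm@counts[k, sub[!isPref], b])
      }
      C <- suppressWarnings(cor(cp, method = "spearman",
                                use = "pairwise.complete.obs"))
      C[!is.finite(C)] <- NA
      acc <- acc + ifelse(is.na(C), 0, C)
      acc2 <- acc2 + ifelse(is.na(C), 0, C^2)
    }
  })
  mu <- acc / nResamples
  se <- sqrt(matrix(pmax(0, acc2 / nResamples - mu^2), nb, nb)) / sqrt(nResamples)
  adjacent <- mu[cbind(seq_len(nb - 1), seq_len(nb - 1) + 1L)]
  tAdj <- (binCenters[-nb] + binCenters[-1]) / 2 / 1000
  slope <- coef(lm(adjacent ~ tAdj))[2]
  perm <- withSeed(deriveSeed(seed, "cp-matrix-perm"),
    replicate(nPerm, coef(lm(sample(adjacent) ~ tAdj))[2]))
  pval <- mean(abs(perm) >= abs(slope))
  new("CPCorrelationMatrix", mean = mu, se = se, binCenters = binCenters,
      adjacent = adjacent, adjacentSlope = c(slope = unname(slope), p = pval),
      nResamples = as.integer(nResamples), nTrialsSub = as.integer(nTrialsSub))
}
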