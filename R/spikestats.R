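# Spike-count statistics: counts as box-kernel convolutions of the 1 ms
# binned spike train, Fano factors, Pearson noise correlations with optional
# shift correction, pair-averaged correlation matrices on the (i - 1/2) T
# bin grid.

# per-trial, per-neuron sorted spike-time lists for a set of sensory neurons
# (times converted to ms relative to stimulus onset)
sensorySpikeLists <- function(ensemble, neurons) {
  on <- ensemble@preMs
  lapply(ensemble@trials, function(tr) {
    keep <- tr$sensId %in% neurons
    split(tr$sensT[keep] - on, factor(tr$sensId[keep], levels = neurons))
  })
}

# counts of 1 ms-binned spikes with bin index in [t - T/2, t + T/2]
# (closed on the bin grid; bins are floor(time))
windowCounts <- function(sorted, centers, T) {
  lo <- centers - T / 2 - 1e-9
  hi <- centers + T / 2 + 1 - 1e-9 # bin b covers [b, b+1)
  findInterval(hi, sorted) - findInterval(lo, sorted)
}

#' Spike counts per neuron, trial and time bin
#'
#' Fixed mode: box-kernel counts of width T centred on each bin. Adjusted
#' mode: for each neuron and bin the window length T' is found by bisection
#' (with linear interpolation of the cumulative cross-trial mean-count
#' function) so that the mean count equals the neuron's trial-averaged
#' stimulus rate times T; windows are clipped to the recorded data.
#'
#' @param ensemble a \code{TrialEnsemble}.
#' @param neurons 0-based sensory neuron ids.
#' @param T nominal window, ms.
#' @param binCenters bin centres, ms from stimulus onset (default the
#'   non-overlapping grid (i - 1/2) T over the stimulus).
#' @param mode "fixed" or "adjusted".
#' @param trials optional trial subset (indices).
#' @return A \code{CountMatrix}.
#' @export
spikeCounts <- function(ensemble, neurons, T = 250, binCenters = NULL,
                        mode = c("fixed", "adjusted"), trials = NULL) {
  mode <- match.arg(mode)
  if (T > ensemble@stimMs + ensemble@preMs - ensemble@recordFromMs)
    stop("count window larger than the recorded trial span")
  if (is.null(binCenters))
    binCenters <- (seq_len(floor(ensemble@stimMs / T)) - 0.5) * T
  if (is.null(trials)) trials <- seq_len(nTrials(ensemble))
  lists <- sensorySpikeLists(ensemble, neurons)[trials]
  nn <- length(neurons); nl <- length(trials); nb <- length(binCenters)
  counts <- array(0, c(nn, nl, nb))
  # spike times binned at 1 ms
  for (l in seq_len(nl)) {
    trl <- lists[[l]]
    for (k in seq_len(nn))
      counts[k, l, ] <- windowCounts(floor(trl[[k]]), binCenters, T)
  }
  windows <- matrix(T, nn, nb)
  if (mode == "adjusted") {
    loLim <- ensemble@recordFromMs - ensemble@preMs
    hiLim <- ensemble@stimMs
    for (k in seq_len(nn)) {
      # trial-averaged rate over the stimulus epoch
      stimCount <- mean(vapply(lists, function(trl)
        sum(trl[[k]] > 0 & trl[[k]] <= ensemble@stimMs), numeric(1)))
      target <- stimCount / ensemble@stimMs * T # = r_k * T
      if (target <= 0) next
      for (b in seq_len(nb)) {
        t0 <- binCenters[b]
        meanCount <- function(Tw) {
          lo <- max(loLim, t0 - Tw / 2); hi <- min(hiLim, t0 + Tw / 2)
          mean(vapply(lists, function(trl) {
            v <- floor(trl[[k]])
            findInterval(hi + 1 - 1e-9, v) - findInterval(lo - 1e-9, v)
          }, numeric(1)))
        }
        Tmax <- 2 * min(t0 - loLim, hiLim - t0)
        if (meanCount(Tmax) < target) {
          Tw <- Tmax
        } else {
          lo <- 0; hi <- Tmax
          for (it in 1:30) {
            mid <- (lo + hi) / 2
            if (meanCount(mid) < target) lo <- mid else hi <- mid
          }
          Tw <- (lo + hi) / 2
        }
        windows[k, b] <- Tw
        lo <- max(loLim, t0 - Tw / 2); hi <- min(hiLim, t0 + Tw / 2)
        for (l in seq_len(nl)) {
          v <- floor(lists[[l]][[k]])
          counts[k, l, b] <- findInterval(hi + 1 - 1e-9, v) -
            findInterval(lo - 1e-9, v)
        }
      }
    }
  }
  new("CountMatrix", counts = counts, binCenters = binCenters, T = T,
      mode = mode, windows = windows, neuronIds = as.integer(neurons))
}

#' Population firing rate, optionally conditioned on choice
#'
#' Instantaneous population rate (box kernel, width T) averaged over
#' trials; with `byChoice = TRUE` the average is split by the recorded
#' choice; trials with choice alpha = beta (population index) are the
#' "preferred" class.
#'
#' @param ensemble a \code{TrialEnsemble}.
#' @param population population name ("E1", "E2", "D1", "D2").
#' @param T smoothing window, ms.
#' @param byChoice split by choice.
#' @return data.frame with tMs (trial time) and rate columns (`rate`, or
#'   `rateChoice1`/`rateChoice2`).
#' @export
populationRate <- function(ensemble, population, T = 50, byChoice = FALSE) {
  pops <- ensemble@populations
  circ <- if (population %in% c("E1", "E2", "Is")) "sensory" else "integration"
  ids <- pops$id[pops$population == population & pops$circuit == circ]
  if (!length(ids)) stop("empty population")
  toMs <- ensemble@preMs + ensemble@stimMs
  field <- if (circ == "sensory") c("sensId", "sensT") else c("intId", "intT")
  traces <- vapply(ensemble@trials, function(tr) {
    sel <- tr[[field[1]]] %in% ids
    rateTrace(tr[[field[2]]][sel], length(ids), toMs, T)
  }, numeric(as.integer(toMs)))
  tMs <- seq_len(as.integer(toMs)) - 0.5
  # rates before the recording start are undefined
  undef <- tMs < ensemble@recordFromMs + T / 2
  if (!byChoice) {
    r <- rowMeans(traces); r[undef] <- NA
    return(data.frame(tMs = tMs, rate = r))
  }
  ch <- as.data.frame(ensemble@labels)$choice
  if (!any(ch == 1) || !any(ch == 2))
    warning("a choice class is empty; conditioned trace undefined")
  r1 <- rowMeans(traces[, ch == 1, drop = FALSE])
  r2 <- rowMeans(traces[, ch == 2, drop = FALSE])
  r1[undef] <- NA; r2[undef] <- NA
  data.frame(tMs = tMs, rateChoice1 = r1, rateChoice2 = r2)
}

# cyclic lag-1 shift predictor of the covariance between trial series a, b
shiftPredictor <- function(a, b) {
  L <- length(a)
  mean((a - mean(a)) * (b[c(2:L, 1)] - mean(b)))
}

# population covariance across trials (1/L normalization, to pair with the
# shift predictor)
popCov <- function(a, b) mean((a - mean(a)) * (b - mean(b)))

#' Spike-count Fano factor
#'
#' FF = Var[n]/Mean[n] across trials per neuron and bin. With
#' `shiftCorrect = TRUE` the cyclic lag-1 cross-trial autocovariance is
#' subtracted from the variance first, removing slow across-trial drift in
#' the firing rate.
#'
#' @param cm a \code{CountMatrix}.
#' @param shiftCorrect logical.
#' @return Matrix [neurons, bins]; bins with zero mean count are NA.
#' @export
fanoFactor <- function(cm, shiftCorrect = FALSE) {
  d <- dim(cm@counts)
  if (d[2] < 2) stop("Fano factor requires >= 2 trials")
  out <- matrix(NA_real_, d[1], d[3])
  for (k in seq_len(d[1])) for (b in seq_len(d[3])) {
    n <- cm@counts[k, , b]
    m <- mean(n)
    if (m == 0) next
    v <- popCov(n, n)
    if (shiftCorrect) v <- v - shiftPredictor(n, n)
    out[k, b] <- v / m
  }
  out
}

#' Pearson spike-count noise correlation between two count series
#'
#' Correlation across trials of two neurons' counts at two times. With
#' `shiftCorrect = TRUE`, the cyclic lag-1 shift predictor is subtracted
#' from the covariance and from each variance before forming the ratio.
#'
#' @param a,b numeric count vectors (one per trial).
#' @param shiftCorrect logical.
#' @return Correlation in [-1, 1]; NA if either variance is not positive.
#' @export
noiseCorrelation <- function(a, b, shiftCorrect = FALSE) {
  if (length(a) < 2) stop("need >= 2 trials")
  va <- popCov(a, a); vb <- popCov(b, b); cab <- popCov(a, b)
  if (shiftCorrect) {
    cab <- cab - shiftPredictor(a, b)
    va <- va - shiftPredictor(a, a)
    vb <- vb - shiftPredictor(b, b)
  }
  if (va <= 0 || vb <= 0) return(NA_real_)
  max(-1, min(1, cab / sqrt(va * vb)))
}

#' Pair-averaged spike-count correlation matrix
#'
#' Pearson correlations across trials, evaluated on the non-overlapping bin
#' grid t_i = (i - 1/2) T over the stimulus epoch, averaged over a pair set
#' of sensory excitatory neurons. Correlations are computed separately per
#' stimulus coherence and averaged with equal weights. The diagonal holds
#' instantaneous correlations, the off-diagonals lagged correlations; the
#' per-pair least-squares slope of the adjacent-bin lagged correlation
#' versus time is also returned (to split pairs into rising vs decaying).
#'
#' @param ensemble a \code{TrialEnsemble}.
#' @param neurons 0-based sensory E neuron ids to form pairs from.
#' @param pairSet "EiEi" (within-population pairs), "EiEj" (across), or
#'   "EE" (all pairs).
#' @param T window, ms.
#' @param weightByTrials average coherences weighted by trial counts
#'   instead of equally.
#' @return A \code{CorrelationMatrix}.
#' @export
correlationMatrix <- function(ensemble, neurons, pairSet = c("EE", "EiEi", "EiEj"),
                              T = 250, weightByTrials = FALSE) {
  pairSet <- match.arg(pairSet)
  if (ensemble@stimMs < 8 * T) stop("stimulus epoch shorter than 8 bins")
  sens <- ensemble@populations[ensemble@populations$circuit == "sensory", ]
  popOf <- sens$population[match(neurons, sens$id)]
  nn <- length(neurons)
  same <- outer(popOf, popOf, "==")
  mask <- switch(pairSet, EiEi = same, EiEj = !same,
                 EE = matrix(TRUE, nn, nn))
  mask[lower.tri(mask, diag = TRUE)] <- FALSE
  if (sum(mask) < 2) stop("fewer than 2 valid pairs")
  lab <- as.data.frame(ensemble@labels)
  cohs <- sort(unique(lab$coherence))
  nb <- 8L
  binCenters <- (seq_len(nb) - 0.5) * T
  acc <- array(0, c(nb, nb)); accW <- 0
  pairAdj <- matrix(0, sum(mask), nb - 1L); adjW <- 0
  for (co in cohs) {
    trialIdx <- which(lab$coherence == co)
    if (length(trialIdx) < 3) next
    cm <- spikeCounts(ensemble, neurons, T = T, binCenters = binCenters,
                      trials = trialIdx)
    w <- if (weightByTrials) length(trialIdx) else 1
    m <- matrix(NA_real_, nb, nb)
    for (i in seq_len(nb)) for (j in i:nb) {
      X <- t(cm@counts[, , i]); Y <- t(cm@counts[, , j])
      suppressWarnings(R <- cor(X, Y))
      if (i == j) {
        m[i, j] <- mean(R[mask], na.rm = TRUE)
      } else {
        # average the two orderings so the matrix is symmetric in (k,t)
        v <- (R + t(R)) / 2
        m[i, j] <- m[j, i] <- mean(v[mask], na.rm = TRUE)
        if (j == i + 1) pairAdj[, i] <- pairAdj[, i] + w * v[mask]
      }
    }
    acc <- acc + w * m; accW <- accW + w; adjW <- adjW + w
  }
  if (accW == 0) stop("no coherence level with enough trials")
  pairAdj <- pairAdj / adjW
  tAdj <- (binCenters[-nb] + binCenters[-1]) / 2 / 1000
  slopes <- apply(pairAdj, 1, function(y)
    if (all(is.finite(y))) coef(lm(y ~ tAdj))[2] else NA_real_)
  new("CorrelationMatrix", mat = acc / accW, binCenters = binCenters, T = T,
      pairSet = pairSet, nPairs = as.integer(sum(mask)),
      pairSlopes = as.numeric(slopes))
}
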