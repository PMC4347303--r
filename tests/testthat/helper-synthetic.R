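# Synthetic trial ensembles built directly from spike data (no simulation),
# so the statistics modules are tested against constructions with known
# ground truth.

# build a TrialEnsemble from a list of per-trial data.frames (id, t) of
# sensory spikes (times in ms from stimulus onset), choices, and optional
# integration spikes
syntheticEnsemble <- function(spikes, choices, nE1 = 2, nE2 = 2,
                              stimMs = 2000, preMs = 0, coherence = 0,
                              intSpikes = NULL, stimTraces = list(),
                              mode = "non-replicate", sigma = 1) {
  n <- length(spikes)
  pops <- data.frame(
    id = c(0:(nE1 + nE2 - 1), 0:3),
    circuit = c(rep("sensory", nE1 + nE2), rep("integration", 4)),
    population = c(rep("E1", nE1), rep("E2", nE2), "D1", "D1", "D2", "D2"),
    group = NA_character_, stringsAsFactors = FALSE)
  trials <- lapply(seq_len(n), function(i) {
    sp <- spikes[[i]]
    it <- if (is.null(intSpikes)) data.frame(id = integer(0), t = numeric(0))
      else intSpikes[[i]]
    list(sensId = as.integer(sp$id), sensT = as.numeric(sp$t) + preMs,
         intId = as.integer(it$id), intT = as.numeric(it$t) + preMs)
  })
  lab <- S4Vectors::DataFrame(choice = as.integer(choices),
    coherence = rep(coherence, length.out = n),
    stimulusId = seq_len(n), stimSeed = seq_len(n),
    bgSeed = seq_len(n), initSeed = seq_len(n))
  new("TrialEnsemble", trials = trials, labels = lab, mode = mode,
      populations = pops,
      stimConfig = stimulusConfig(coherence = 0, sigma = sigma,
                                  durationMs = stimMs),
      stimTraces = stimTraces, preMs = preMs, stimMs = stimMs,
      recordFromMs = 0, masterSeed = 1)
}

# per-trial Poisson spikes for a set of neurons at given rates (sp/s)
poissonTrials <- function(nTrials, rates, stimMs = 2000) {
  lapply(seq_len(nTrials), function(i) {
    do.call(rbind, lapply(seq_along(rates), function(k) {
      nsp <- rpois(1, rates[k] * stimMs / 1000)
      if (nsp == 0) return(data.frame(id = integer(0), t = numeric(0)))
      data.frame(id = k - 1L, t = sort(runif(nsp, 0, stimMs)))
    }))
  })
}

# naive reference implementations (independent oracles)
naiveCount <- function(times, center, T) {
  b <- floor(times)
  sum(b >= center - T / 2 & b <= center + T / 2)
}
naivePearson <- function(a, b) {
  ma <- mean(a); mb <- mean(b)
  num <- sum((a - ma) * (b - mb))
  den <- sqrt(sum((a - ma)^2) * sum((b - mb)^2))
  if (den == 0) NA_real_ else num / den
}
naiveFano <- function(n) {
  if (mean(n) == 0) return(NA_real_)
  mean((n - mean(n))^2) / mean(n)
}
naiveRoc <- function(pref, null) {
  tot <- 0
  for (p in pref) for (q in null)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pref) * length(null))
}

# small deterministic model fixtures shared across test files (built once)
.fixtures <- new.env(parent = emptyenv())
fixtureNetwork <- function(bFB = 0, scale = 0.25, gFF = NULL, seed = 1,
                           heterogeneous = FALSE) {
  key <- paste("net", bFB, scale, gFF %||% "d", seed, heterogeneous)
  if (is.null(.fixtures[[key]])) {
    cfg <- networkConfig(bFB = bFB, scale = scale, gFF = gFF)
    if (heterogeneous) cfg <- makeHeterogeneous(cfg, seed = seed)
    .fixtures[[key]] <- buildNetwork(cfg, seed = seed)
  }
  .fixtures[[key]]
}
fixtureBatch <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}
`%||%` <- hierCP:::`%||%`
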