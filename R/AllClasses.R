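setClassUnion("listOrNULL", c("list", "NULL"))

#' NetworkConfig: full parameterization of the two-circuit model
#'
#' Holds sizes, connection probabilities, synaptic efficacies and the
#' coupling parameters of the hierarchical network, including the
#' dimensionless top-down feedback strength \code{bFB} (synaptic weight
#' 0.0668 nS x bFB), the background-input arrangement
#' (\code{backgroundMode}: global, one external population X shared by E1
#' and E2; or local, X split into two exclusive halves at unchanged total
#' drive), an optional overall size \code{scale} (efficacies are rescaled by
#' 1/scale so mean inputs are preserved), and an optional per-neuron
#' heterogeneity map (see \code{\link{makeHeterogeneous}}).
#'
#' @slot params nested parameter list, see \code{\link{defaultParameters}}.
#' @slot bFB dimensionless feedback strength, >= 0 (0 = feedforward-only).
#' @slot backgroundMode "global" or "local".
#' @slot scale positive size scaling factor (1 = full size).
#' @slot heterogeneity NULL or a list with per-sensory-neuron feedback and
#'   stimulus-modulation factors (slots `group`, `bFBfac`, `sigStimFac`,
#'   `sigIndFac`).
#' @exportClass NetworkConfig
setClass("NetworkConfig",
  representation(params = "list", bFB = "numeric",
    backgroundMode = "character", scale = "numeric",
    heterogeneity = "listOrNULL"))

setValidity("NetworkConfig", function(object) {
  p <- object@params
  msg <- character()
  probs <- c(p$sensory$p, p$sensory$pX, p$coupling$pFF, p$coupling$pFB)
  if (any(probs < 0 | probs > 1)) msg <- c(msg, "connection probabilities must be in [0,1]")
  effs <- c(p$sensory$gEE, p$sensory$gEI, p$sensory$gII, p$sensory$gX,
            p$coupling$gFF, p$coupling$gFBbase)
  if (any(effs < 0)) msg <- c(msg, "synaptic efficacies must be >= 0")
  if (object@bFB < 0) msg <- c(msg, "bFB must be >= 0")
  if (!object@backgroundMode %in% c("global", "local"))
    msg <- c(msg, "backgroundMode must be 'global' or 'local'")
  if (object@scale <= 0) msg <- c(msg, "scale must be > 0")
  for (lif in list(p$sensory$lifE, p$sensory$lifI, p$integration$lifE, p$integration$lifI)) {
    if (lif$Vth <= lif$Vres) msg <- c(msg, "spike threshold must exceed reset")
    if (lif$tref < 0) msg <- c(msg, "refractory period must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Network: a realized hierarchical network
#'
#' A built network: realized connection lists (a pure function of the
#' connectivity seed), per-neuron parameters in simulator layout, and a
#' population table.
#'
#' @slot config the \code{NetworkConfig} used.
#' @slot seed connectivity seed.
#' @slot arrays internal simulator arrays (CSR connectivity and parameters).
#' @slot populations data.frame: id (0-based), circuit, population, group.
#' @exportClass Network
setClass("Network",
  representation(config = "NetworkConfig", seed = "numeric",
    arrays = "list", populations = "data.frame"))

#' StimulusConfig: time-varying stimulus current parameters
#'
#' The stimulus into each sensory neuron k of population beta is the current
#' I = I0 (1 + s_beta(t) + s_ind,k(t)) with s_beta(t) = gamma_beta c +
#' sigma_stim z_beta(t) and s_ind,k(t) = sigma_ind z_ind,k(t), where z are
#' independent unit-variance Ornstein-Uhlenbeck processes (tau = 20 ms) and
#' gamma_E2 = -gamma_E1. sigma_stim = sigma_ind = 0.212 sigma.
#'
#' @slot I0 mean zero-coherence input, nA.
#' @slot coherence signed motion coherence in [-1, 1].
#' @slot gamma additional relative input at coherence 1 for E1 (E2 = -gamma).
#' @slot sigma dimensionless strength of temporal modulations.
#' @slot tauStim OU time constant, ms.
#' @slot durationMs stimulus duration, ms.
#' @slot replicate logical: frozen stimulus replayed on every trial.
#' @exportClass StimulusConfig
setClass("StimulusConfig",
  representation(I0 = "numeric", coherence = "numeric", gamma = "numeric",
    sigma = "numeric", tauStim = "numeric", durationMs = "numeric",
    replicate = "logical"))

setValidity("StimulusConfig", function(object) {
  msg <- character()
  if (object@tauStim <= 0) msg <- c(msg, "tauStim must be > 0")
  if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
  if (abs(object@coherence) > 1) msg <- c(msg, "coherence must be in [-1, 1]")
  if (object@durationMs < 0) msg <- c(msg, "durationMs must be >= 0")
  if (length(msg)) msg else TRUE
})

#' StimulusTrace: one realized stimulus
#'
#' The frozen realization of the common modulation paths of the two sensory
#' populations plus the seed from which every per-neuron individual path is
#' reconstructed bit-identically. Replaying a trace injects identical
#' currents into every neuron on every trial.
#'
#' @slot config the generating \code{StimulusConfig}.
#' @slot id stimulus id within a bank.
#' @slot stimSeed integer seed of this realization.
#' @slot zE1,zE2 unit-variance OU common paths at 1 ms resolution.
#' @exportClass StimulusTrace
setClass("StimulusTrace",
  representation(config = "StimulusConfig", id = "integer",
    stimSeed = "numeric", zE1 = "numeric", zE2 = "numeric"))

#' TrialEnsemble: spike rasters plus per-trial labels
#'
#' The common currency of all statistics: per-trial spike times (ms,
#' trial-relative, recorded populations only) and per-trial labels (choice,
#' coherence, stimulus id and seeds). Produced by \code{\link{runBatch}};
#' externally recorded data can be wrapped in the same container.
#'
#' @slot trials list, one element per trial, each with integer `sensId`,
#'   numeric `sensT`, integer `intId`, numeric `intT` (0-based ids; times in
#'   ms from trial start).
#' @slot labels DataFrame with columns choice, coherence, stimulusId,
#'   stimSeed, bgSeed, initSeed.
#' @slot mode "replicate" or "non-replicate".
#' @slot populations population table of the generating network.
#' @slot stimConfig the StimulusConfig used.
#' @slot stimTraces list of StimulusTrace (replicate bank, or per-trial
#'   common paths in non-replicate mode).
#' @slot preMs,stimMs protocol epochs (ms); stimulus onset is at preMs.
#' @slot recordFromMs recording start (ms from trial start).
#' @slot masterSeed the batch master seed.
#' @exportClass TrialEnsemble
setClass("TrialEnsemble",
  representation(trials = "list", labels = "DataFrame", mode = "character",
    populations = "data.frame", stimConfig = "StimulusConfig",
    stimTraces = "list", preMs = "numeric", stimMs = "numeric",
    recordFromMs = "numeric", masterSeed = "numeric"))

setValidity("TrialEnsemble", function(object) {
  msg <- character()
  if (length(object@trials) != nrow(object@labels))
    msg <- c(msg, "one label row per trial required")
  if (!object@mode %in% c("replicate", "non-replicate"))
    msg <- c(msg, "mode must be 'replicate' or 'non-replicate'")
  if (length(msg)) msg else TRUE
})

#' CountMatrix: spike counts per neuron, trial and time bin
#'
#' Counts are the discrete convolution of the 1 ms binned spike train with a
#' box kernel of width T (window (t - T/2, t + T/2], half-open). In adjusted
#' mode the per-neuron, per-bin window length T' is searched so that the
#' cross-trial mean count equals the neuron's trial-averaged rate times T.
#'
#' @slot counts numeric array [neurons, trials, bins].
#' @slot binCenters bin centres, ms from stimulus onset.
#' @slot T nominal window length, ms.
#' @slot mode "fixed" or "adjusted".
#' @slot windows realized window lengths [neurons, bins] (adjusted mode).
#' @slot neuronIds 0-based neuron ids (rows of counts).
#' @exportClass CountMatrix
setClass("CountMatrix",
  representation(counts = "array", binCenters = "numeric", T = "numeric",
    mode = "character", windows = "matrix", neuronIds = "integer"))

#' CorrelationMatrix: pair-averaged spike-count correlations on a bin grid
#'
#' Pearson correlations across trials of spike counts at bin pairs
#' (t_i, t_j), t_i = (i - 1/2) T, averaged over a pair set; the diagonal
#' holds instantaneous correlations, off-diagonals lagged correlations.
#'
#' @slot mat matrix of pair-averaged correlations.
#' @slot binCenters bin centres, ms from stimulus onset.
#' @slot T window length, ms.
#' @slot pairSet description of the averaged pair set.
#' @slot nPairs number of pairs averaged.
#' @slot pairSlopes per-pair least-squares slope of the adjacent-bin lagged
#'   correlation versus time (used to split pairs into rising/decaying).
#' @exportClass CorrelationMatrix
setClass("CorrelationMatrix",
  representation(mat = "matrix", binCenters = "numeric", T = "numeric",
    pairSet = "character", nPairs = "integer", pairSlopes = "numeric"))

#' CPTimeCourse: per-neuron choice probability versus time
#'
#' CP_k(t; T) is the area under the ROC curve classifying the spike counts
#' in window (t - T/2, t + T/2] by the trial's choice (preferred versus
#' non-preferred); 0.5 is chance. Bins with fewer than 5 trials in either
#' choice class are masked (NA).
#'
#' @slot cp matrix [neurons, bins].
#' @slot binCenters bin centres, ms from stimulus onset.
#' @slot T window length, ms.
#' @slot mode "fixed" or "adjusted".
#' @slot neuronIds 0-based ids.
#' @slot preferred preferred choice (1 or 2) per neuron.
#' @slot nPref,nNull trials per choice class.
#' @exportClass CPTimeCourse
setClass("CPTimeCourse",
  representation(cp = "matrix", binCenters = "numeric", T = "numeric",
    mode = "character", neuronIds = "integer", preferred = "integer",
    nPref = "integer", nNull = "integer"))

#' CPCorrelationMatrix: across-neuron stability of CP over time
#'
#' C(t_i, t_j) is the Spearman rank correlation across neurons of CP
#' measured at two time bins, averaged over trial resamples; it quantifies
#' whether the ordering of neurons by CP is maintained through the trial.
#'
#' @slot mean resample-averaged matrix C(t_i, t_j).
#' @slot se resample standard errors.
#' @slot binCenters bin centres, ms.
#' @slot adjacent adjacent-bin series C(t_i, t_{i+1}).
#' @slot adjacentSlope least-squares slope of the adjacent series vs time
#'   (per s) and its permutation p-value.
#' @slot nResamples,nTrialsSub resampling specification.
#' @exportClass CPCorrelationMatrix
setClass("CPCorrelationMatrix",
  representation(mean = "matrix", se = "matrix", binCenters = "numeric",
    adjacent = "numeric", adjacentSlope = "numeric",
    nResamples = "integer", nTrialsSub = "integer"))

#' PsychKernel: psychophysical reverse-correlation kernel
#'
#' The choice-conditioned difference of the average evidence fluctuation,
#' kernel(t) = <d(t) | choice 1> - <d(t) | choice 2> with
#' d(t) = s_E1(t) - s_E2(t), measuring when stimulus fluctuations influence
#' the decision. The integration window is the onset-anchored interval
#' containing a fixed fraction (default 85%) of the kernel's area.
#'
#' @slot kernel kernel amplitude per 1 ms step (units of modulation s.d.).
#' @slot tMs time from stimulus onset, ms.
#' @slot nChoice1,nChoice2 trials per choice.
#' @slot window integration window, s.
#' @slot fraction area fraction defining the window.
#' @exportClass PsychKernel
setClass("PsychKernel",
  representation(kernel = "numeric", tMs = "numeric",
    nChoice1 = "integer", nChoice2 = "integer",
    window = "numeric", fraction = "numeric"))

#' PsychometricFit: Weibull fit of percent correct versus coherence
#'
#' P(c) = 1 - 0.5 exp(-(c/alpha)^beta), fitted by maximum likelihood on
#' binomial counts; the discrimination threshold is the coherence where the
#' fitted curve reaches 82% correct (close to, but not exactly, alpha).
#'
#' @slot coherences,nTrials,nCorrect the fitted data.
#' @slot alpha,beta Weibull scale and slope.
#' @slot threshold coherence at 82% correct.
#' @slot vcov parameter covariance (log scale).
#' @slot converged logical.
#' @exportClass PsychometricFit
setClass("PsychometricFit",
  representation(coherences = "numeric", nTrials = "integer",
    nCorrect = "integer", alpha = "numeric", beta = "numeric",
    threshold = "numeric", vcov = "matrix", converged = "logical"))

#' BoundAnalysis: non-absorbing bound crossings and reversals
#'
#' Classifies each trial by whether either decision population's smoothed
#' rate crossed a bound theta during the stimulus, and whether the final
#' choice matches the first-crossing population (consistent) or not
#' (reversal). Confidence is the D1 - D2 rate difference averaged over the
#' second half of the stimulus, signed toward the chosen population.
#'
#' @slot table DataFrame per trial: class, firstCrossMs, firstCrossPop,
#'   confidence.
#' @slot theta bound, sp/s.
#' @slot T rate smoothing window, ms.
#' @exportClass BoundAnalysis
setClass("BoundAnalysis",
  representation(table = "DataFrame", theta = "numeric", T = "numeric"))
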