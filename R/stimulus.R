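# Stimulus model: coherence drive plus common and individual OU modulations,
# delivered as injected current so that replicate stimuli carry literally
# zero stimulus-borne trial-to-trial variability.

#' Create a stimulus configuration
#'
#' @param coherence signed motion coherence c in [-1, 1]; positive values
#'   favour the direction preferred by E1.
#' @param sigma dimensionless strength of temporal modulations; the common
#'   and individual modulation amplitudes are sigma_stim = sigma_ind =
#'   0.212 sigma.
#' @param gamma additional relative input at coherence 1 into E1
#'   (gamma_E2 = -gamma exactly). The default is the package's calibrated
#'   value placing the sensory circuit in its approximately linear
#'   coherence-response regime.
#' @param I0 mean zero-coherence input, nA.
#' @param tauStim OU time constant, ms.
#' @param durationMs stimulus duration, ms.
#' @param replicate logical; TRUE replays one frozen realization every trial.
#' @return A validated \code{StimulusConfig}.
#' @export
#' @examples
#' stimulusConfig(coherence = 0.032, sigma = 1)
stimulusConfig <- function(coherence = 0, sigma = 1, gamma = 1,
                           I0 = 0.08, tauStim = 20, durationMs = 2000,
                           replicate = FALSE) {
  obj <- new("StimulusConfig", I0 = I0, coherence = coherence, gamma = gamma,
             sigma = sigma, tauStim = tauStim, durationMs = durationMs,
             replicate = replicate)
  validObject(obj)
  obj
}

#' Stationary unit-variance Ornstein-Uhlenbeck path
#'
#' Exact-discretization update x(t+dt) = x e^(-dt/tau) +
#' sqrt(1 - e^(-2 dt/tau)) eta, so the path has zero mean and unit variance
#' at any step size; the initial value is drawn from the stationary
#' distribution.
#'
#' @param tau time constant, ms.
#' @param duration path duration, ms.
#' @param dt sampling step, ms (must not exceed tau).
#' @param seed integer seed; identical seeds give identical paths.
#' @return Numeric vector of length `duration/dt` (empty for duration 0).
#' @export
#' @examples
#' x <- ouPath(20, 1000, 1, seed = 1)
ouPath <- function(tau, duration, dt = 1, seed = 1) {
  if (dt > tau) stop("dt must not exceed tau (discretization)")
  n <- as.integer(round(duration / dt))
  .ouPathCpp(n, tau, dt, seed)
}

#' Generate one stimulus realization
#'
#' Draws the common modulation paths z_E1(t), z_E2(t) (mutually independent
#' unit-variance OU processes) from sub-seeds of the stimulus seed; the
#' per-neuron individual paths z_ind,k(t) are not materialized but
#' reconstructed bit-identically from (stimSeed, k) whenever needed.
#'
#' @param config a \code{StimulusConfig}.
#' @param stimSeed integer seed of this realization.
#' @param id stimulus id (bank bookkeeping).
#' @return A \code{StimulusTrace}.
#' @export
makeStimulus <- function(config, stimSeed, id = 1L) {
  n <- as.integer(round(config@durationMs))
  new("StimulusTrace", config = config, id = as.integer(id),
      stimSeed = stimSeed,
      zE1 = .ouPathCpp(n, config@tauStim, 1, deriveSeed(stimSeed, "common-z", 1)),
      zE2 = .ouPathCpp(n, config@tauStim, 1, deriveSeed(stimSeed, "common-z", 2)))
}

#' Generate a bank of frozen replicate stimuli
#'
#' @param config a \code{StimulusConfig}.
#' @param nStimuli bank size (the classical design uses 100 distinct
#'   replicate stimuli, each presented over many repeated trials).
#' @param seed integer seed; the bank is a pure function of (config, seed).
#' @return List of \code{StimulusTrace} with ids 1..nStimuli.
#' @export
replicateBank <- function(config, nStimuli, seed = 1) {
  stopifnot(nStimuli >= 1)
  lapply(seq_len(nStimuli), function(i)
    makeStimulus(config, deriveSeed(seed, "replicate-bank", i), id = i))
}

#' Reconstruct realized stimulus currents for given neurons
#'
#' Returns the injected current I_k(t) = I0 (1 + gamma_beta c +
#' sigma_stim z_beta(t) + sigma_ind z_ind,k(t)) in nA at 1 ms resolution,
#' identical to what the simulator injects.
#'
#' @param trace a \code{StimulusTrace}.
#' @param network the \code{Network} receiving it (defines populations and
#'   per-neuron heterogeneity).
#' @param neurons 0-based sensory neuron ids.
#' @return Matrix [time, neurons], nA.
#' @export
stimulusCurrents <- function(trace, network, neurons) {
  st <- stimArrays(trace, network)
  n <- length(trace@zE1)
  out <- matrix(0, n, length(neurons))
  popS <- network@arrays$popS
  for (j in seq_along(neurons)) {
    k <- neurons[j]
    zc <- if (popS[k + 1L] == 0L) trace@zE1 else if (popS[k + 1L] == 1L) trace@zE2 else 0
    zi <- if (st$sigmaInd[k + 1L] > 0)
      .indOuPathCpp(trace@stimSeed, k, n, trace@config@tauStim, 1) else 0
    if (popS[k + 1L] < 2L)
      out[, j] <- trace@config@I0 * (1 + st$gammaC[k + 1L] +
        st$sigmaStim[k + 1L] * zc + st$sigmaInd[k + 1L] * zi)
  }
  out
}

# per-neuron stimulus arrays for the simulator: gamma*c (signed by
# population), sigma_stim and sigma_ind with heterogeneity factors applied
stimArrays <- function(trace, network) {
  cfg <- trace@config
  popS <- network@arrays$popS
  Ns <- network@arrays$Ns
  base <- 0.212 * cfg@sigma
  gammaC <- ifelse(popS == 0L, cfg@gamma * cfg@coherence,
            ifelse(popS == 1L, -cfg@gamma * cfg@coherence, 0))
  sigS <- ifelse(popS < 2L, base, 0)
  sigI <- ifelse(popS < 2L, base, 0)
  het <- network@config@heterogeneity
  if (!is.null(het)) {
    sigS <- sigS * het$sigStimFac
    sigI <- sigI * het$sigIndFac
  }
  list(I0 = cfg@I0, gammaC = gammaC, sigmaStim = sigS, sigmaInd = sigI,
       zE1 = trace@zE1, zE2 = trace@zE2, stimSeed = trace@stimSeed,
       tauStim = cfg@tauStim, Ns = Ns)
}
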