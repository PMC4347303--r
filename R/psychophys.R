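# Psychophysical reverse correlation, integration window, psychometric
# curves and the threshold-versus-window trade-off.

#' Psychophysical reverse-correlation kernel
#'
#' kernel(t) = <d(t) | choice 1> - <d(t) | choice 2> with d(t) the common
#' evidence fluctuation s_E1(t) - s_E2(t) (the controlled evidence
#' variable; per-neuron individual modulations average out and are not part
#' of the evidence). A flat kernel indicates perfect (uniform) temporal
#' weighting of evidence; an early-peaked decaying kernel indicates
#' transient integration.
#'
#' @param ensemble a \code{TrialEnsemble} with stored stimulus traces.
#' @param fraction area fraction defining the integration window.
#' @param smoothMs optional box smoothing of the kernel, ms.
#' @return A \code{PsychKernel}.
#' @export
psychKernel <- function(ensemble, fraction = 0.85, smoothMs = 0) {
  if (!length(ensemble@stimTraces))
    stop("ensemble carries no stimulus traces; reconstruct them from seeds")
  lab <- as.data.frame(ensemble@labels)
  cfg <- ensemble@stimConfig
  sigStim <- 0.212 * cfg@sigma
  n <- as.integer(cfg@durationMs)
  traceFor <- function(i) {
    tr <- if (ensemble@mode == "replicate")
      ensemble@stimTraces[[lab$stimulusId[i]]] else ensemble@stimTraces[[i]]
    sigStim * (tr@zE1 - tr@zE2) # common part of s_E1 - s_E2 at c = 0
  }
  s1 <- numeric(n); s2 <- numeric(n)
  n1 <- 0L; n2 <- 0L
  for (i in seq_len(nrow(lab))) {
    d <- traceFor(i)
    if (lab$choice[i] == 1) { s1 <- s1 + d; n1 <- n1 + 1L }
    else { s2 <- s2 + d; n2 <- n2 + 1L }
  }
  if (n1 == 0 || n2 == 0) stop("one choice class is empty")
  kern <- s1 / n1 - s2 / n2
  if (smoothMs > 1) {
    k <- rep(1 / smoothMs, smoothMs)
    kern <- as.numeric(stats::filter(kern, k, sides = 2))
  }
  win <- integrationWindow(kern, fraction = fraction)
  new("PsychKernel", kernel = kern, tMs = seq_len(n) - 0.5,
      nChoice1 = n1, nChoice2 = n2, window = win, fraction = fraction)
}

#' Integration window of a psychophysical kernel
#'
#' The shortest onset-anchored interval whose cumulative kernel area
#' reaches `fraction` of the total area. Negative excursions are clipped to
#' zero before the area computation by default (kernels are onset-peaked
#' and non-negative in expectation); both choices are exposed.
#'
#' @param kernel numeric kernel sampled at `dtMs` resolution (or a
#'   \code{PsychKernel}).
#' @param fraction area fraction (default 0.85).
#' @param clipNegative clip negative excursions to zero.
#' @param dtMs kernel sampling step, ms.
#' @return Window length in seconds (NA if the total area is not positive).
#' @export
#' @examples
#' integrationWindow(rep(1, 2000)) # flat kernel over 2 s -> 1.7 s
integrationWindow <- function(kernel, fraction = 0.85, clipNegative = TRUE,
                              dtMs = 1) {
  if (is(kernel, "PsychKernel")) kernel <- kernel@kernel
  k <- kernel
  k[is.na(k)] <- 0
  if (clipNegative) k <- pmax(k, 0)
  tot <- sum(k)
  if (tot <= 0) { warning("kernel total area not positive"); return(NA_real_) }
  cs <- cumsum(k) / tot
  ix <- which(cs >= fraction)[1]
  # linear interpolation within the crossing step
  prev <- if (ix > 1) cs[ix - 1] else 0
  frac <- (fraction - prev) / (cs[ix] - prev)
  (ix - 1 + frac) * dtMs / 1000
}

#' Psychometric curve of the network
#'
#' Runs batches at each coherence level and reports the percentage of
#' correct choices (choice matching the sign of the coherence; zero
#' coherence carries no correct answer and is excluded).
#'
#' @param network a \code{Network}.
#' @param coherences positive coherence levels.
#' @param nTrialsPerLevel trials per level.
#' @param masterSeed seed (per-level sub-seeds derived from it).
#' @param sigma stimulus modulation strength.
#' @param preMs pre-stimulus interval, ms.
#' @param stimulusConfigFn optional function(coherence) returning the
#'   \code{StimulusConfig} for a level.
#' @return data.frame: coherence, n, nCorrect, pctCorrect, lo95, hi95.
#' @export
psychometricCurve <- function(network, coherences, nTrialsPerLevel,
                              masterSeed = 1, sigma = 1, preMs = 3000,
                              stimulusConfigFn = NULL) {
  stopifnot(all(coherences > 0))
  if (nTrialsPerLevel < 20)
    warning("fewer than 20 trials per level: wide confidence intervals")
  rows <- lapply(seq_along(coherences), function(i) {
    cfg <- if (is.null(stimulusConfigFn))
      stimulusConfig(coherence = coherences[i], sigma = sigma)
    else stimulusConfigFn(coherences[i])
    ens <- runBatch(network, cfg, nTrialsPerLevel, mode = "non-replicate",
                    masterSeed = deriveSeed(masterSeed, "psycho-level", i),
                    preMs = preMs, recordFromMs = preMs + cfg@durationMs - 100)
    ch <- as.data.frame(ens@labels)$choice
    nc <- sum(ch == 1) # positive coherence favours E1/D1
    ci <- binom.test(nc, nTrialsPerLevel)$conf.int
    data.frame(coherence = coherences[i], n = nTrialsPerLevel, nCorrect = nc,
               pctCorrect = 100 * nc / nTrialsPerLevel,
               lo95 = 100 * ci[1], hi95 = 100 * ci[2])
  })
  do.call(rbind, rows)
}

#' Fit a Weibull psychometric function
#'
#' Maximum-likelihood fit of P(c) = 1 - 0.5 exp(-(c/alpha)^beta) to
#' binomial correct counts (two-parameter form; asymptotes 50% and 100%).
#' The discrimination threshold is the coherence where the fitted curve
#' yields 82% correct, solved exactly: alpha (ln(0.5/0.18))^(1/beta).
#'
#' @param curve data.frame with columns coherence, n, nCorrect (as returned
#'   by \code{\link{psychometricCurve}}).
#' @return A \code{PsychometricFit}.
#' @export
#' @examples
#' d <- data.frame(coherence = c(.05, .1, .2, .4), n = 100,
#'                 nCorrect = c(55, 70, 92, 100))
#' fitWeibull(d)
fitWeibull <- function(curve) {
  if (nrow(curve) < 4) stop("need at least 4 coherence levels")
  c0 <- curve$coherence; n <- curve$n; k <- curve$nCorrect
  nll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    p <- 1 - 0.5 * exp(-(c0 / a)^b)
    p <- pmin(1 - 1e-12, pmax(1e-12, p))
    -sum(k * log(p) + (n - k) * log(1 - p))
  }
  # moment-style start: alpha near the ~82%-correct coherence
  pObs <- k / n
  aStart <- if (any(pObs >= 0.82)) c0[which(pObs >= 0.82)[1]] else max(c0)
  fit <- optim(c(log(aStart), log(1.5)), nll, hessian = TRUE)
  a <- exp(fit$par[1]); b <- exp(fit$par[2])
  vc <- tryCatch(solve(fit$hessian), error = function(e) matrix(NA, 2, 2))
  thr <- a * log(0.5 / 0.18)^(1 / b)
  new("PsychometricFit", coherences = c0, nTrials = as.integer(n),
      nCorrect = as.integer(k), alpha = a, beta = b, threshold = thr,
      vcov = vc, converged = fit$convergence == 0)
}

#' Weibull psychometric function
#' @param c coherence.
#' @param alpha,beta Weibull scale and slope.
#' @return Probability correct.
#' @export
weibullP <- function(c, alpha, beta) 1 - 0.5 * exp(-(c / alpha)^beta)

#' Log-log slope of discrimination threshold versus integration window
#'
#' Least-squares regression of log(threshold) on log(window) across
#' feedback strengths. Perfect integration of evidence over the window
#' predicts a slope of -0.5 (threshold falls as one over the square root of
#' the integration time).
#'
#' @param thresholds,windows numeric vectors (same length >= 2, one point
#'   per feedback strength).
#' @return List: slope, intercept, se, ci95 (slope), fit (the lm).
#' @export
#' @examples
#' w <- c(0.4, 0.8, 1.6); thresholdVsWindow(w^-0.5, w)$slope # -0.5
thresholdVsWindow <- function(thresholds, windows) {
  ok <- is.finite(thresholds) & is.finite(windows) &
    thresholds > 0 & windows > 0
  if (sum(ok) < 2) stop("need >= 2 (threshold, window) points")
  fit <- lm(log(thresholds[ok]) ~ log(windows[ok]))
  sl <- coef(fit)[2]
  se <- tryCatch(sqrt(vcov(fit)[2, 2]), error = function(e) NA_real_)
  list(slope = unname(sl), intercept = unname(coef(fit)[1]), se = se,
       ci95 = unname(sl + c(-1.96, 1.96) * se), fit = fit)
}
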