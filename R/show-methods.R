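# show() methods for the main classes

setMethod("show", "NetworkConfig", function(object) {
  sz <- populationSizes(object)
  cat("NetworkConfig\n")
  cat(sprintf("  sensory: E1 %d + E2 %d + I %d, X %d (%s background)\n",
              sz$nE1, sz$nE2, sz$nIs, sz$nX, object@backgroundMode))
  cat(sprintf("  integration: D1 %d + D2 %d + Dn %d + I %d\n",
              sz$nD1, sz$nD2, sz$nDn, sz$nIi))
  cat(sprintf("  feedback strength bFB = %g (gFB = %.4f nS), gFF = %g nS, scale = %g\n",
              object@bFB, object@params$coupling$gFBbase * object@bFB,
              object@params$coupling$gFF, object@scale))
  if (!is.null(object@heterogeneity))
    cat("  heterogeneous stimulus/feedback groups (S+/-FB+/-)\n")
})

setMethod("show", "Network", function(object) {
  cat(sprintf("Network (seed %g): %d sensory + %d integration neurons, %d sparse links\n",
              object@seed, object@arrays$Ns, object@arrays$Ni,
              length(object@arrays$senTgt) + length(object@arrays$xTgt) +
                length(object@arrays$ffTgt) + length(object@arrays$fbTgt)))
  show(object@config)
})

setMethod("show", "StimulusConfig", function(object) {
  cat(sprintf("StimulusConfig: c = %g, sigma = %g (sigma_stim = %.4f), gamma = %g, I0 = %g nA, %g ms%s\n",
              object@coherence, object@sigma, 0.212 * object@sigma,
              object@gamma, object@I0, object@durationMs,
              if (object@replicate) ", replicate" else ""))
})

setMethod("show", "TrialEnsemble", function(object) {
  lab <- as.data.frame(object@labels)
  cat(sprintf("TrialEnsemble: %d trials (%s), choice split %d/%d, pre %g ms + stim %g ms\n",
              nTrials(object), object@mode, sum(lab$choice == 1),
              sum(lab$choice == 2), object@preMs, object@stimMs))
})

setMethod("show", "CountMatrix", function(object) {
  d <- dim(object@counts)
  cat(sprintf("CountMatrix: %d neurons x %d trials x %d bins (T = %g ms, %s windows)\n",
              d[1], d[2], d[3], object@T, object@mode))
})

setMethod("show", "CorrelationMatrix", function(object) {
  cat(sprintf("CorrelationMatrix (%s, %d pairs, T = %g ms): instantaneous mean %.4f\n",
              object@pairSet, object@nPairs, object@T,
              mean(diag(object@mat), na.rm = TRUE)))
})

setMethod("show", "CPTimeCourse", function(object) {
  cat(sprintf("CPTimeCourse: %d neurons x %d bins (T = %g ms, %s), grand mean CP %.3f\n",
              nrow(object@cp), ncol(object@cp), object@T, object@mode,
              mean(object@cp, na.rm = TRUE)))
})

setMethod("show", "CPCorrelationMatrix", function(object) {
  cat(sprintf("CPCorrelationMatrix: %d bins, %d resamples of %d trials; adjacent-bin slope %.3f /s (p = %.3f)\n",
              nrow(object@mean), object@nResamples, object@nTrialsSub,
              object@adjacentSlope["slope"], object@adjacentSlope["p"]))
})

setMethod("show", "PsychKernel", function(object) {
  cat(sprintf("PsychKernel: %d ms epoch, %d/%d trials per choice, %.0f%%-area window %.3f s\n",
              length(object@kernel), object@nChoice1, object@nChoice2,
              100 * object@fraction, object@window))
})

setMethod("show", "PsychometricFit", function(object) {
  cat(sprintf("PsychometricFit: alpha = %.4f, beta = %.2f, threshold(82%%) = %.4f%s\n",
              object@alpha, object@beta, object@threshold,
              if (object@converged) "" else " (did not converge)"))
})

setMethod("show", "BoundAnalysis", function(object) {
  tab <- table(object@table$class)
  cat(sprintf("BoundAnalysis (theta = %g sp/s, T = %g ms): %s\n",
              object@theta, object@T,
              paste(names(tab), as.integer(tab), sep = " = ", collapse = ", ")))
})
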