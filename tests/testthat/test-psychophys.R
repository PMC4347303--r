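test_that("integration window matches closed forms", {
  # flat kernel over 2 s -> 0.85 x 2 s = 1.7 s
  expect_equal(integrationWindow(rep(1, 2000)), 1.7, tolerance = 1e-3)
  # exponential kernel: window = tau ln(1/0.15)
  tau <- 300
  k <- exp(-(seq_len(20000) - 0.5) / tau)
  expect_equal(integrationWindow(k), tau * log(1 / 0.15) / 1000,
               tolerance = 1e-3)
  expect_warning(w <- integrationWindow(rep(0, 100)), "area")
  expect_true(is.na(w))
})

test_that("psychophysical kernel is flat for a perfect integrator and null for random choices", {
  withr::local_seed(15)
  cfg <- stimulusConfig(sigma = 1, durationMs = 2000)
  traces <- lapply(1:400, function(i) makeStimulus(cfg, stimSeed = i * 13, id = i))
  d <- vapply(traces, function(tr) 0.212 * (tr@zE1 - tr@zE2),
              numeric(2000))
  # perfect integrator: choice = sign of integrated evidence
  chInt <- ifelse(colSums(d) > 0, 1L, 2L)
  spikes <- replicate(400, data.frame(id = integer(0), t = numeric(0)),
                      simplify = FALSE)
  ensInt <- syntheticEnsemble(spikes, chInt, stimTraces = traces)
  kInt <- psychKernel(ensInt)
  # flat: mean of first and last quarter agree within 25%
  q1 <- mean(kInt@kernel[1:500]); q4 <- mean(kInt@kernel[1501:2000])
  expect_gt(q1, 0)
  expect_lt(abs(q1 - q4) / q1, 0.35)
  expect_gt(kInt@window, 1.5) # close to the flat-kernel 1.7 s
  # random choices: kernel ~ 0
  chRnd <- sample(rep(1:2, 200))
  kRnd <- psychKernel(syntheticEnsemble(spikes, chRnd, stimTraces = traces))
  expect_lt(mean(abs(kRnd@kernel)), 3 * 0.212 * sqrt(2) / sqrt(100))
  # early-weighted decision rule gives a decaying kernel and shorter window
  chEarly <- ifelse(colSums(d[1:500, ]) > 0, 1L, 2L)
  kEarly <- psychKernel(syntheticEnsemble(spikes, chEarly, stimTraces = traces))
  expect_lt(kEarly@window, kInt@window)
})

test_that("Weibull closed form and parameter recovery hold", {
  # P(alpha) = 1 - 0.5 e^-1 for any beta
  expect_equal(weibullP(0.2, 0.2, 1.3), 1 - 0.5 * exp(-1))
  expect_equal(weibullP(0.2, 0.2, 4), 1 - 0.5 * exp(-1))
  withr::local_seed(16)
  aStar <- 0.12; bStar <- 1.6
  cg <- c(0.02, 0.05, 0.1, 0.2, 0.4)
  k <- rbinom(5, 500, weibullP(cg, aStar, bStar))
  fit <- fitWeibull(data.frame(coherence = cg, n = 500, nCorrect = k))
  expect_true(fit@converged)
  expect_equal(fit@alpha, aStar, tolerance = 0.1)
  # threshold solves P = 0.82 exactly
  expect_equal(weibullP(fit@threshold, fit@alpha, fit@beta), 0.82,
               tolerance = 1e-6)
  # step data: threshold bracketed by the two coherences
  kStep <- c(250, 250, 500, 500, 500)
  fStep <- fitWeibull(data.frame(coherence = cg, n = 500, nCorrect = kStep))
  expect_gt(fStep@threshold, 0.05)
  expect_lt(fStep@threshold, 0.12)
  expect_error(fitWeibull(data.frame(coherence = 1:3, n = 10, nCorrect = 1:3)),
               "4 coherence")
})

test_that("threshold-window log-log slope recovers known power laws", {
  w <- c(0.3, 0.5, 0.9, 1.5)
  expect_equal(thresholdVsWindow(w^(-0.5), w)$slope, -0.5, tolerance = 1e-10)
  expect_equal(thresholdVsWindow(0.2 * w^(-1), w)$slope, -1, tolerance = 1e-10)
  expect_error(thresholdVsWindow(1, 1), "points")
})
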