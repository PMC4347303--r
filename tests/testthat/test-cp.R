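test_that("ROC area equals brute-force pair enumeration", {
  expect_equal(rocArea(c(1, 2, 3), c(1, 2, 3)), 0.5) # identical multisets
  expect_equal(rocArea(c(5, 6), c(1, 2)), 1)          # perfectly separated
  expect_equal(rocArea(c(2, 3), c(1, 2)), 0.875)      # half-credit ties
  # property sweep: all small integer count vectors
  withr::local_seed(5)
  for (i in 1:50) {
    p <- sample(0:5, sample(1:8, 1), replace = TRUE)
    q <- sample(0:5, sample(1:8, 1), replace = TRUE)
    expect_equal(rocArea(p, q), naiveRoc(p, q))
  }
})

test_that("shuffled choice labels give chance-level CP", {
  withr::local_seed(9)
  spikes <- poissonTrials(60, rates = rep(12, 4), stimMs = 2000)
  ens <- syntheticEnsemble(spikes, choices = sample(rep(1:2, 30)),
                           nE1 = 2, nE2 = 2)
  ct <- cpTimecourse(ens, neurons = 0:3, T = 250,
                     binCenters = c(375, 1125, 1875))
  expect_equal(mean(ct@cp), 0.5, tolerance = 0.06)
  # preferred-choice assignment is structural
  expect_equal(ct@preferred, c(1L, 1L, 2L, 2L))
})

test_that("CP detects choice-predictive counts with the expected sign", {
  withr::local_seed(10)
  # E1 neurons fire more before choice 1, E2 before choice 2
  choices <- rep(1:2, 40)
  spikes <- lapply(choices, function(ch) {
    r <- c(if (ch == 1) c(18, 18) else c(10, 10),
           if (ch == 2) c(18, 18) else c(10, 10))
    do.call(rbind, lapply(0:3, function(k) {
      nsp <- rpois(1, r[k + 1] * 2)
      data.frame(id = k, t = sort(runif(nsp, 0, 2000)))
    }))
  })
  ens <- syntheticEnsemble(spikes, choices, nE1 = 2, nE2 = 2)
  ct <- cpTimecourse(ens, neurons = 0:3, T = 500, binCenters = c(250, 1750))
  expect_true(all(ct@cp > 0.7)) # all neurons CP toward their preferred choice
  # bins with < 5 trials per class are masked
  ensFew <- syntheticEnsemble(spikes[c(1:6, 8)], choices[c(1:6, 8)],
                              nE1 = 2, nE2 = 2)
  ctFew <- cpTimecourse(ensFew, neurons = 0:3, T = 500, binCenters = 250)
  expect_true(all(is.na(ctFew@cp)))
})

test_that("unit selection applies the five rules in order", {
  withr::local_seed(11)
  mk <- function(nTrials, rate, choices) {
    spikes <- poissonTrials(nTrials, rates = c(rate, 20, 20, 20), stimMs = 2000)
    syntheticEnsemble(spikes, choices, nE1 = 2, nE2 = 2)
  }
  # exactly 20 zero-coherence trials -> excluded (strictly more required)
  sel20 <- selectUnits(mk(20, 20, rep(1:2, 10)))
  expect_length(sel20$included, 0)
  expect_equal(unname(sel20$excludedBy["trials"]), 4L)
  # only 4 non-preferred choices -> excluded by the choice rule
  sel4 <- selectUnits(mk(30, 20, c(rep(1, 26), rep(2, 4))))
  expect_false(0 %in% sel4$included)   # E1 neuron lacks non-preferred
  # 0.5 sp/s neuron excluded by the rate rule, others kept
  selR <- selectUnits(mk(30, 0.5, rep(1:2, 15)))
  expect_false(0 %in% selR$included)
  expect_true(all(c(1, 2, 3) %in% selR$included))
})

test_that("population CP averages a seeded neuron sample with s.e.m.", {
  withr::local_seed(13)
  spikes <- poissonTrials(40, rates = rep(15, 4), stimMs = 2000)
  ens <- syntheticEnsemble(spikes, choices = rep(1:2, 20), nE1 = 2, nE2 = 2)
  expect_warning(populationCP(ens, nNeurons = 10, T = 500,
                              binCenters = c(250, 1000, 1750)), "eligible")
  pc <- suppressWarnings(populationCP(ens, nNeurons = 10, T = 500,
                                      binCenters = c(250, 1000, 1750)))
  expect_length(pc$mean, 3)
  expect_true(all(is.finite(pc$sem)))
  expect_setequal(pc$neurons, 0:3)
})

test_that("CP correlation matrix is 1 for a shared ranking and ~0 for noise", {
  withr::local_seed(14)
  # neurons with widely different rates: CP ranking driven by rate-linked
  # choice modulation that is stable over time
  choices <- rep(1:2, 30)
  gains <- c(1.02, 1.3, 1.02, 1.3) # per-neuron choice modulation
  spikes <- lapply(choices, function(ch) {
    do.call(rbind, lapply(0:3, function(k) {
      pref <- if (k < 2) 1 else 2
      r <- 15 * (if (ch == pref) gains[k + 1] else 1)
      nsp <- rpois(1, r * 2)
      data.frame(id = k, t = sort(runif(nsp, 0, 2000)))
    }))
  })
  ens <- syntheticEnsemble(spikes, choices, nE1 = 2, nE2 = 2)
  m <- cpCorrelationMatrix(ens, neurons = 0:3, T = 250, nTrialsSub = 40,
                           nResamples = 60, seed = 2, nPerm = 200)
  expect_equal(dim(m@mean), c(8L, 8L))
  expect_true(all(diag(m@mean) > 0.99))
  expect_length(m@adjacent, 7)
  expect_error(cpCorrelationMatrix(ens, 0:3, nTrialsSub = 1000),
               "exceeds")
})
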