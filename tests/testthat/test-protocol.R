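test_that("choice readout picks the higher decision rate and breaks ties reproducibly", {
  # D1 = ids 0..1, D2 = ids 2..3 (synthetic 2+2 decision circuit)
  mkTrial <- function(d1T, d2T)
    list(intId = c(rep(0L, length(d1T)), rep(2L, length(d2T))),
         intT = c(d1T, d2T))
  tr <- mkTrial(seq(1960, 1995, by = 5), c(1970))
  expect_equal(readChoice(tr, nD1 = 2, nD2 = 2, stimEndMs = 2000), 1L)
  tr2 <- mkTrial(c(1970), seq(1960, 1995, by = 5))
  expect_equal(readChoice(tr2, nD1 = 2, nD2 = 2, stimEndMs = 2000), 2L)
  # exact tie: seeded fair coin, reproducible
  trT <- mkTrial(c(1970, 1980), c(1975, 1985))
  c1 <- readChoice(trT, 2, 2, 2000, tieSeed = 3)
  expect_identical(c1, readChoice(trT, 2, 2, 2000, tieSeed = 3))
  flips <- vapply(1:200, function(s) readChoice(trT, 2, 2, 2000, tieSeed = s),
                  integer(1))
  expect_gt(mean(flips == 1), 0.35)
  expect_lt(mean(flips == 1), 0.65)
})

test_that("batches keep replicate bookkeeping and are reproducible", {
  net <- fixtureNetwork(bFB = 0, scale = 0.1)
  cfg <- stimulusConfig(sigma = 1, durationMs = 200)
  ens <- runBatch(net, cfg, nTrials = 12, mode = "replicate", nStimuli = 4,
                  masterSeed = 3, preMs = 100, recordFromMs = 0)
  lab <- as.data.frame(trialLabels(ens))
  expect_equal(sort(unique(lab$stimulusId)), 1:4)
  expect_true(all(table(lab$stimulusId) == 3))
  # same stimulus id means identical stimulus seed
  expect_equal(length(unique(lab$stimSeed[lab$stimulusId == 2])), 1L)
  # non-replicate: all stimulus seeds distinct
  ens2 <- runBatch(net, cfg, nTrials = 10, mode = "non-replicate",
                   masterSeed = 3, preMs = 100, recordFromMs = 0)
  expect_equal(length(unique(as.data.frame(trialLabels(ens2))$stimSeed)), 10L)
  # full reproducibility from the master seed
  ens3 <- runBatch(net, cfg, nTrials = 10, mode = "non-replicate",
                   masterSeed = 3, preMs = 100, recordFromMs = 0)
  expect_identical(ens2@trials, ens3@trials)
  expect_identical(as.data.frame(trialLabels(ens2)),
                   as.data.frame(trialLabels(ens3)))
})

test_that("replicate-stimulus exclusion uses a strict 95% bound", {
  mk <- function(fracs, nPer = 100) {
    choices <- unlist(lapply(fracs, function(f)
      c(rep(1L, round(f * nPer)), rep(2L, nPer - round(f * nPer)))))
    n <- length(choices)
    spikes <- replicate(n, data.frame(id = integer(0), t = numeric(0)),
                        simplify = FALSE)
    ens <- syntheticEnsemble(spikes, choices, mode = "replicate")
    ens@labels$stimulusId <- rep(seq_along(fracs), each = nPer)
    ens
  }
  res <- filterReplicateStimuli(mk(c(0.96, 0.95, 0.5, 0.03)))
  expect_setequal(res$excluded, c(1, 4)) # 96% and 97% consistent
  expect_setequal(res$kept, c(2, 3))     # 95% is kept (strict inequality)
  ensNR <- syntheticEnsemble(list(data.frame(id = integer(0), t = numeric(0))),
                             choices = 1)
  expect_error(filterReplicateStimuli(ensNR), "replicate")
})

test_that("heterogeneous split preserves group sizes and input-current s.d.", {
  cfg <- makeHeterogeneous(networkConfig(bFB = 1, scale = 0.25), seed = 4)
  het <- cfg@heterogeneity
  sz <- hierCP:::populationSizes(cfg)
  gE1 <- het$group[seq_len(sz$nE1)]
  expect_true(all(table(gE1) == sz$nE1 / 4))
  gE2 <- het$group[sz$nE1 + seq_len(sz$nE2)]
  expect_true(all(table(gE2) == sz$nE2 / 4))
  # S-FB- neurons receive neither common modulation nor top-down weight
  idx <- which(het$group == "S-FB-")
  expect_true(all(het$sigStimFac[idx] == 0))
  expect_true(all(het$bFBfac[idx] == 0))
  # per-neuron stimulus-current s.d. identical across groups (exact
  # compensation: sigma_stim^2 + sigma_ind^2 is constant)
  tot <- sqrt(het$sigStimFac^2 + het$sigIndFac^2)
  e <- seq_len(sz$nE1 + sz$nE2)
  expect_true(all(abs(tot[e] - sqrt(2)) < 1e-12))
  # FB+ neurons carry twice the nominal feedback weight; population mean
  # equals the homogeneous network
  expect_equal(mean(het$bFBfac[e]), 1)
  net <- buildNetwork(cfg, seed = 1)
  expect_setequal(unique(net@arrays$fbW), c(0, 2 * 0.0668 / 0.25))
  expect_error(makeHeterogeneous(cfg), "already")
})

test_that("bound-crossing trials are classified into the three classes", {
  # synthetic decision rasters: 2 + 2 decision neurons
  burst <- function(id, from, to, rate) {
    n <- round((to - from) / 1000 * rate)
    data.frame(id = id, t = seq(from, to, length.out = max(n, 1)))
  }
  # trial 1: D1 crosses at ~800 ms and stays -> consistent (choice 1)
  t1 <- rbind(burst(0, 800, 2000, 60), burst(1, 800, 2000, 60))
  # trial 2: D1 crosses early then D2 takes over -> reversal (choice 2)
  t2 <- rbind(burst(0, 600, 1000, 60), burst(1, 600, 1000, 60),
              burst(2, 1200, 2000, 60), burst(3, 1200, 2000, 60))
  # trial 3: nothing crosses -> no-crossing
  t3 <- burst(0, 0, 2000, 5)
  spikes <- replicate(3, data.frame(id = integer(0), t = numeric(0)),
                      simplify = FALSE)
  ens <- syntheticEnsemble(spikes, choices = c(1, 2, 1),
                           intSpikes = list(t1, t2, t3))
  ba <- classifyBoundTrials(ens, theta = 30, T = 50)
  expect_equal(as.character(ba@table$class),
               c("consistent", "reversal", "no-crossing"))
  expect_equal(ba@table$firstCrossPop[1:2], c(1L, 1L))
  expect_gt(ba@table$confidence[1], 0)
  # a vacuous bound yields 100% no-crossing
  baInf <- classifyBoundTrials(ens, theta = 1e6)
  expect_true(all(ba@table$class[3] == "no-crossing"))
  expect_true(all(as.character(baInf@table$class) == "no-crossing"))
})
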