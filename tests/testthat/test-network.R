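test_that("realized connectivity matches the specified probabilities", {
  net <- fixtureNetwork(bFB = 1, scale = 1)
  # E1 -> E1 at p = 0.2: expected 800 x 799 x 0.2, within 4 binomial s.d.
  n <- connectionCount(net, "E1", "E1")
  expected <- 800 * 799 * 0.2
  sdev <- sqrt(800 * 799 * 0.2 * 0.8)
  expect_lt(abs(n - expected), 4 * sdev)
  # X -> sensory at pX = 0.32 covers E and I
  nx <- connectionCount(net, "X", "E1") + connectionCount(net, "X", "E2") +
    connectionCount(net, "X", "Is")
  expect_lt(abs(nx - 1000 * 2000 * 0.32), 4 * sqrt(1000 * 2000 * 0.32 * 0.68))
  # all-to-all integration circuit without self-connections
  expect_equal(connectionCount(net, "D1", "D1"), 240 * 239)
  expect_equal(connectionCount(net, "D1", "D2"), 240 * 240)
  # topographic coupling: no E1 -> D2 or D1 -> E2 links
  expect_equal(connectionCount(net, "E1", "D2"), 0)
  expect_equal(connectionCount(net, "D1", "E2"), 0)
  expect_gt(connectionCount(net, "E1", "D1"), 0)
})

test_that("efficacy structure carries w+/w- and the printed values", {
  net <- fixtureNetwork(bFB = 1, scale = 1)
  a <- net@arrays
  src <- rep(seq_along(diff(a$senPtr)) - 1L, diff(a$senPtr))
  popS <- a$popS
  sPop <- popS[src + 1L]; tPop <- popS[a$senTgt + 1L]
  wEE_same <- a$senW[sPop == 0 & tPop == 0]
  wEE_cross <- a$senW[sPop == 0 & tPop == 1]
  expect_equal(unique(wEE_same), 0.76 * 1.3)
  expect_equal(unique(wEE_cross), 0.76 * 0.7)
  expect_equal(unique(a$senW[sPop < 2 & tPop == 2]), 1.52)
  expect_equal(unique(a$senW[sPop == 2]), 12.6)
  expect_equal(unique(a$xW), 1.71)
  # each realized feedback synapse has efficacy 0.0668 x bFB
  expect_equal(unique(a$fbW), 0.0668)
  # integration block weights: w+ = 1.6 within D1/D2; compensating
  # depression elsewhere onto selective populations
  f <- 240 / 1600
  wm <- 1 - f * (1.6 - 1) / (1 - f)
  expect_equal(a$wBlock[1, ], c(1.6, wm, wm))
  expect_equal(a$wBlock[3, ], c(1, 1, 1))
})

test_that("connectivity is a pure function of the seed and honours p = 0", {
  cfg <- networkConfig(scale = 0.1)
  n1 <- buildNetwork(cfg, seed = 5)
  n2 <- buildNetwork(cfg, seed = 5)
  expect_identical(n1@arrays$senTgt, n2@arrays$senTgt)
  expect_identical(n1@arrays$xTgt, n2@arrays$xTgt)
  n3 <- buildNetwork(cfg, seed = 6)
  expect_false(identical(n1@arrays$senTgt, n3@arrays$senTgt))
  # p = 0 pathways: empty coupling still simulates
  p <- defaultParameters(); p$coupling$pFF <- 0; p$coupling$pFB <- 0
  net0 <- buildNetwork(networkConfig(scale = 0.1, params = p), seed = 1)
  expect_length(net0@arrays$ffTgt, 0)
  st <- makeStimulus(stimulusConfig(sigma = 1, durationMs = 200), 3)
  tr <- runTrial(net0, st, preMs = 100, recordFromMs = 0)
  expect_true(tr$choice %in% 1:2)
})

test_that("bFB = 0 yields a purely feedforward hierarchy", {
  net <- fixtureNetwork(bFB = 0, scale = 0.1)
  expect_true(all(net@arrays$fbW == 0))
})

test_that("invalid configurations are rejected", {
  p <- defaultParameters(); p$sensory$p <- 1.3
  expect_error(networkConfig(params = p), "probabilit")
  p2 <- defaultParameters(); p2$sensory$gEE <- -1
  expect_error(networkConfig(params = p2), "efficac")
  expect_error(networkConfig(bFB = -1), "bFB")
  expect_error(networkConfig(backgroundMode = "x"), "backgroundMode")
})

test_that("poisson background matches its nominal statistics", {
  st <- poissonBackground(12.5, 1000, 5000, seed = 3)
  counts <- lengths(st)
  total <- sum(counts)
  expect_lt(abs(total - 62500), 4 * sqrt(62500))
  # Fano of per-source counts ~ 1
  expect_equal(var(counts) / mean(counts), 1, tolerance = 0.15)
  expect_identical(poissonBackground(0, 5, 1000, 1),
                   rep(list(numeric(0)), 5))
  expect_error(poissonBackground(-1, 5, 1000), "rate")
  # inter-event intervals exponential (KS test at alpha = 0.01)
  long <- poissonBackground(50, 1, 200000, seed = 8)[[1]]
  isi <- diff(long)
  ks <- suppressWarnings(stats::ks.test(isi, "pexp", rate = 50 / 1000))
  expect_gt(ks$p.value, 0.01)
})

test_that("local background mode preserves per-neuron drive and splits X", {
  netL <- buildNetwork(networkConfig(backgroundMode = "local", scale = 0.25),
                       seed = 2)
  netG <- fixtureNetwork(bFB = 0, scale = 0.25, seed = 2)
  aL <- netL@arrays; aG <- netG@arrays
  # mean in-degree from X onto E neurons unchanged
  inDegL <- tabulate(aL$xTgt + 1L, nbins = aL$Ns)
  inDegG <- tabulate(aG$xTgt + 1L, nbins = aG$Ns)
  e <- aL$popS < 2
  expect_equal(mean(inDegL[e]), mean(inDegG[e]), tolerance = 0.05)
  # halves project exclusively to their population
  half <- aL$nX %/% 2
  srcL <- rep(seq_along(diff(aL$xPtr)) - 1L, diff(aL$xPtr))
  tgtPop <- aL$popS[aL$xTgt + 1L]
  expect_true(all(tgtPop[srcL < half & tgtPop < 2] == 0))
  expect_true(all(tgtPop[srcL >= half & tgtPop < 2] == 1))
})
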