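test_that("window counts follow the binned box-kernel convention", {
  sp <- list(data.frame(id = 0L, t = c(10, 60, 110)))
  ens <- syntheticEnsemble(sp, choices = 1, nE1 = 1, nE2 = 1, stimMs = 500)
  cm <- spikeCounts(ens, neurons = 0L, T = 100, binCenters = 60)
  expect_equal(cm@counts[1, 1, 1], 3) # bins 10, 60, 110 all inside [10, 110]
  # empty raster -> all-zero counts
  ens0 <- syntheticEnsemble(list(data.frame(id = integer(0), t = numeric(0))),
                            choices = 1, nE1 = 1, nE2 = 1, stimMs = 500)
  cm0 <- spikeCounts(ens0, neurons = 0L, T = 100, binCenters = c(60, 250))
  expect_true(all(cm0@counts == 0))
  expect_error(spikeCounts(ens, neurons = 0L, T = 5000), "larger")
})

test_that("counts, Pearson and Fano agree exactly with naive references", {
  withr::local_seed(7)
  for (rep in 1:5) {
    nTr <- sample(5:20, 1)
    spikes <- poissonTrials(nTr, rates = runif(4, 2, 30), stimMs = 1000)
    ens <- syntheticEnsemble(spikes, choices = rep(1:2, length.out = nTr),
                             nE1 = 2, nE2 = 2, stimMs = 1000)
    centers <- c(125, 375, 625)
    cm <- spikeCounts(ens, neurons = 0:3, T = 250, binCenters = centers)
    for (k in 1:4) for (b in 1:3) {
      ref <- vapply(seq_len(nTr), function(l) {
        sp <- spikes[[l]]
        naiveCount(sp$t[sp$id == k - 1], centers[b], 250)
      }, numeric(1))
      expect_equal(cm@counts[k, , b], ref)
    }
    # Pearson and Fano against naive formulas
    a <- cm@counts[1, , 1]; b2 <- cm@counts[2, , 1]
    expect_equal(noiseCorrelation(a, b2), naivePearson(a, b2), tolerance = 1e-12)
    ff <- fanoFactor(cm)
    expect_equal(ff[1, 1], naiveFano(a), tolerance = 1e-12)
  }
})

test_that("Poisson counts give Fano factor 1 and shift correction removes drift", {
  withr::local_seed(21)
  n <- rpois(5000, 8)
  cmLike <- new("CountMatrix", counts = array(n, c(1, 5000, 1)),
                binCenters = 125, T = 250, mode = "fixed",
                windows = matrix(250, 1, 1), neuronIds = 0L)
  expect_equal(fanoFactor(cmLike)[1, 1], 1, tolerance = 0.05)
  # linear across-trial rate drift: raw FF inflated, corrected FF ~ 1
  lam <- seq(4, 16, length.out = 4000)
  nd <- rpois(4000, lam)
  cmD <- new("CountMatrix", counts = array(nd, c(1, 4000, 1)),
             binCenters = 125, T = 250, mode = "fixed",
             windows = matrix(250, 1, 1), neuronIds = 0L)
  expect_gt(fanoFactor(cmD)[1, 1], 1.5)
  expect_equal(fanoFactor(cmD, shiftCorrect = TRUE)[1, 1], 1, tolerance = 0.1)
  # identical counts every trial -> FF 0
  cmC <- new("CountMatrix", counts = array(5, c(1, 10, 1)), binCenters = 125,
             T = 250, mode = "fixed", windows = matrix(250, 1, 1),
             neuronIds = 0L)
  expect_equal(fanoFactor(cmC)[1, 1], 0)
})

test_that("noise correlation behaves at its analytic anchors", {
  withr::local_seed(8)
  a <- rpois(5000, 10)
  expect_equal(noiseCorrelation(a, a), 1)
  b <- rpois(5000, 10)
  expect_lt(abs(noiseCorrelation(a, b)), 0.03)
  # common doubly-stochastic modulation: correlation matches the
  # Monte-Carlo oracle of the construction
  lam <- 10 * (1 + 0.5 * rnorm(5000))
  lam <- pmax(lam, 0)
  x <- rpois(5000, lam); y <- rpois(5000, lam)
  rObs <- noiseCorrelation(x, y)
  # oracle: corr = var(lam)/(var(lam) + mean(lam)) for shared-rate Poisson
  rOracle <- var(lam) / (var(lam) + mean(lam))
  expect_gt(rObs, 0)
  expect_equal(rObs, rOracle, tolerance = 0.1)
  # drifting shared rate: shift correction removes the slow component
  lam2 <- seq(5, 15, length.out = 4000)
  x2 <- rpois(4000, lam2); y2 <- rpois(4000, lam2)
  expect_gt(noiseCorrelation(x2, y2), 0.2)
  expect_lt(abs(noiseCorrelation(x2, y2, shiftCorrect = TRUE)), 0.1)
  expect_true(is.na(noiseCorrelation(rep(2, 10), rpois(10, 5))))
})

test_that("adjusted windows equal the nominal length for stationary rasters", {
  withr::local_seed(31)
  spikes <- poissonTrials(60, rates = c(20, 20, 0.5, 20), stimMs = 2000)
  ens <- syntheticEnsemble(spikes, choices = rep(1:2, 30), nE1 = 2, nE2 = 2)
  cmA <- spikeCounts(ens, neurons = c(0L, 1L), T = 250, mode = "adjusted")
  expect_true(all(abs(cmA@windows - 250) / 250 < 0.15))
  # fixed and adjusted modes agree within Monte-Carlo error
  cmF <- spikeCounts(ens, neurons = c(0L, 1L), T = 250, mode = "fixed")
  mF <- apply(cmF@counts, c(1, 3), mean)
  mA <- apply(cmA@counts, c(1, 3), mean)
  expect_equal(mA, mF, tolerance = 0.15)
})

test_that("correlation matrix recovers independence and common modulation", {
  withr::local_seed(12)
  # independent neurons -> matrix ~ 0 everywhere
  spikes <- poissonTrials(80, rates = rep(15, 6), stimMs = 2000)
  ens <- syntheticEnsemble(spikes, choices = rep(1:2, 40), nE1 = 3, nE2 = 3)
  cmat <- correlationMatrix(ens, neurons = 0:5, pairSet = "EE", T = 250)
  expect_lt(max(abs(cmat@mat)), 0.15)
  expect_equal(cmat@nPairs, 15L)
  expect_equal(cmat@mat, t(cmat@mat), tolerance = 1e-12)
  # shared gain fluctuation within populations -> positive within-pair corr
  spikes2 <- lapply(1:80, function(i) {
    g1 <- exp(rnorm(1, 0, 0.5)); g2 <- exp(rnorm(1, 0, 0.5))
    do.call(rbind, lapply(0:5, function(k) {
      r <- 15 * (if (k < 3) g1 else g2)
      nsp <- rpois(1, r * 2)
      data.frame(id = k, t = sort(runif(nsp, 0, 2000)))
    }))
  })
  ens2 <- syntheticEnsemble(spikes2, choices = rep(1:2, 40), nE1 = 3, nE2 = 3)
  within <- correlationMatrix(ens2, 0:5, pairSet = "EiEi", T = 250)
  across <- correlationMatrix(ens2, 0:5, pairSet = "EiEj", T = 250)
  expect_gt(mean(diag(within@mat)), 0.3)
  expect_lt(abs(mean(diag(across@mat))), 0.15)
})

test_that("population rate averages counts over neurons and conditions on choice", {
  # 4 neurons firing regularly at 10 sp/s
  spikes <- lapply(1:6, function(i)
    do.call(rbind, lapply(0:3, function(k)
      data.frame(id = k, t = seq(50, 1950, by = 100)))))
  ens <- syntheticEnsemble(spikes, choices = rep(1:2, 3), nE1 = 2, nE2 = 2)
  pr <- populationRate(ens, "E1", T = 200)
  mid <- pr$rate[pr$tMs > 300 & pr$tMs < 1700]
  expect_true(all(abs(mid - 10) < 1e-9))
  byCh <- populationRate(ens, "E1", T = 200, byChoice = TRUE)
  expect_true(all(abs(byCh$rateChoice1[byCh$tMs > 300 & byCh$tMs < 1700] - 10) < 1e-9))
})
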