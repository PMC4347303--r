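# Network construction: sensory circuit, integration circuit, coupling.

# evaluate expr under a local R RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Create a network configuration
#'
#' @param bFB dimensionless top-down feedback strength (0-6); the feedback
#'   synaptic weight is 0.0668 nS x bFB.
#' @param backgroundMode "global" (one shared external population X) or
#'   "local" (X split into two halves projecting exclusively to E1 and E2,
#'   at unchanged per-neuron mean and variance of background drive; a
#'   bottom-up correlation source).
#' @param scale overall size factor; populations are scaled and synaptic
#'   efficacies divided by `scale` so that mean inputs are preserved.
#' @param gFF feedforward efficacy override (nS, at scale 1).
#' @param params full parameter list, see \code{\link{defaultParameters}}.
#' @return A validated \code{NetworkConfig}.
#' @export
#' @examples
#' cfg <- networkConfig(bFB = 1)
networkConfig <- function(bFB = 0, backgroundMode = "global", scale = 1,
                          gFF = NULL, params = defaultParameters()) {
  if (!is.null(gFF)) params$coupling$gFF <- gFF
  obj <- new("NetworkConfig", params = params, bFB = bFB,
             backgroundMode = backgroundMode, scale = scale,
             heterogeneity = NULL)
  validObject(obj)
  obj
}

# realized population sizes under the config's scale
populationSizes <- function(config) {
  s <- config@scale
  ps <- config@params$sensory$sizes
  pi <- config@params$integration$sizes
  r4 <- function(x) max(4L, as.integer(round(x / 4) * 4))
  list(
    nE1 = r4(ps[["E1"]] * s), nE2 = r4(ps[["E2"]] * s),
    nIs = max(1L, as.integer(round(ps[["I"]] * s))),
    nX = max(1L, as.integer(round(ps[["X"]] * s))),
    nD1 = r4(pi[["D1"]] * s), nD2 = r4(pi[["D2"]] * s),
    nDn = max(1L, as.integer(round(pi[["Dn"]] * s))),
    nIi = max(1L, as.integer(round(pi[["I"]] * s)))
  )
}

# sample a sparse pathway: for each source, Bernoulli(p) links to targets
# (0-based indices); returns list(ptr, tgt) in CSR-by-source layout
sampleCsr <- function(nSrc, targets0, p, noSelf = FALSE, srcOffset = 0L) {
  tgt <- vector("list", nSrc)
  nt <- length(targets0)
  for (i in seq_len(nSrc)) {
    hit <- targets0[runif(nt) < p]
    if (noSelf) hit <- hit[hit != (i - 1L + srcOffset)]
    tgt[[i]] <- hit
  }
  lens <- lengths(tgt)
  list(ptr = c(0L, cumsum(lens)), tgt = as.integer(unlist(tgt)))
}

#' Build the sensory circuit
#'
#' Realizes the balanced random EI network: within each pathway block,
#' neuron pairs are linked independently with probability p; efficacies of
#' within-population excitatory links are scaled by w+ and of
#' across-population links by w-; the external population X connects with
#' probability pX. The realization is mirror-symmetric between the two
#' selective populations: the E1-related block patterns are reused for the
#' corresponding E2 blocks (under the index map E1_i <-> E2_i), so the
#' frozen network is exactly invariant under swapping the two stimulus
#' directions and carries no built-in choice bias; only trial-varying
#' inputs break the symmetry. Connection lists are a pure function of the
#' seed.
#'
#' @param config a \code{NetworkConfig}.
#' @param seed connectivity seed.
#' @return A list with CSR connectivity, per-neuron parameters and sizes.
#' @export
buildSensoryCircuit <- function(config, seed) {
  p <- config@params; sn <- p$sensory; sz <- populationSizes(config)
  sc <- config@scale
  nE <- sz$nE1
  Ns <- sz$nE1 + sz$nE2 + sz$nIs
  popS <- c(rep(0L, sz$nE1), rep(1L, sz$nE2), rep(2L, sz$nIs))
  isInh <- popS == 2L
  iIds <- (2L * nE):(Ns - 1L)
  withSeed(deriveSeed(seed, "sensory-connectivity"), {
    # block patterns (E2 blocks mirror the E1 blocks)
    within <- sampleCsr(nE, 0:(nE - 1L), sn$p, noSelf = TRUE)       # E1->E1
    cross <- sampleCsr(nE, 0:(nE - 1L), sn$p)                       # E1->E2
    eToI <- sampleCsr(nE, iIds, sn$p)                               # E1->I
    iToE <- sampleCsr(sz$nIs, 0:(nE - 1L), sn$p)                    # I->E1
    iToI <- sampleCsr(sz$nIs, iIds, sn$p, noSelf = TRUE,
                      srcOffset = 2L * nE)                          # I->I
    rowOf <- function(csr, i) {
      lo <- csr$ptr[i] + 1L; hi <- csr$ptr[i + 1L]
      if (hi < lo) integer(0) else csr$tgt[lo:hi]
    }
    tgt <- vector("list", Ns); wl <- vector("list", Ns)
    for (i in seq_len(nE)) {
      a <- rowOf(within, i); c2 <- rowOf(cross, i); d <- rowOf(eToI, i)
      # E1 source i
      tgt[[i]] <- c(a, c2 + nE, d)
      wl[[i]] <- c(rep(sn$gEE * sn$wPlus, length(a)),
                   rep(sn$gEE * sn$wMinus, length(c2)),
                   rep(sn$gEI, length(d)))
      # mirrored E2 source i
      tgt[[nE + i]] <- c(c2, a + nE, d)
      wl[[nE + i]] <- c(rep(sn$gEE * sn$wMinus, length(c2)),
                        rep(sn$gEE * sn$wPlus, length(a)),
                        rep(sn$gEI, length(d)))
    }
    for (i in seq_len(sz$nIs)) {
      g <- rowOf(iToE, i); h <- rowOf(iToI, i)
      tgt[[2L * nE + i]] <- c(g, g + nE, h)
      wl[[2L * nE + i]] <- rep(sn$gII, 2L * length(g) + length(h))
    }
    rec <- list(ptr = c(0L, cumsum(lengths(tgt))),
                tgt = as.integer(unlist(tgt)))
    w <- as.numeric(unlist(wl))
    # External population X. The X -> E2 block mirrors X -> E1 under a
    # half-rotation of the source indices, so both populations receive
    # exactly the same background in-degree sequence (no static drive
    # asymmetry) while sharing only the chance fraction of actual sources.
    half <- sz$nX %/% 2L
    xTgt <- vector("list", sz$nX)
    for (i in seq_len(sz$nX)) xTgt[[i]] <- integer(0)
    if (config@backgroundMode == "global") {
      pat <- lapply(seq_len(sz$nX), function(i) which(runif(nE) < sn$pX) - 1L)
      for (i in seq_len(sz$nX)) {
        j <- (i - 1L + half) %% sz$nX + 1L
        xTgt[[i]] <- c(pat[[i]], pat[[j]] + nE)
      }
    } else {
      # local mode: the halves project exclusively to their E population
      # with doubled probability (per-neuron mean and variance of the
      # background drive unchanged; shared-input fraction within a
      # population doubles, across populations vanishes)
      pLoc <- min(1, sn$pX * sz$nX / half)
      for (i in seq_len(half)) {
        e1T <- which(runif(nE) < pLoc) - 1L
        xTgt[[i]] <- e1T
        xTgt[[i + half]] <- e1T + nE
      }
    }
    # inhibitory targets: independent draws (shared by construction)
    for (i in seq_len(sz$nX))
      xTgt[[i]] <- c(xTgt[[i]], iIds[runif(sz$nIs) < sn$pX])
    xc <- list(ptr = c(0L, cumsum(lengths(xTgt))),
               tgt = as.integer(unlist(xTgt)))
    xw <- rep(sn$gX, length(xc$tgt))
    list(Ns = Ns, popS = popS, sIsInh = isInh,
      sCm = ifelse(isInh, sn$lifI$Cm, sn$lifE$Cm),
      sGl = ifelse(isInh, sn$lifI$gL, sn$lifE$gL),
      sEl = ifelse(isInh, sn$lifI$EL, sn$lifE$EL),
      sVth = ifelse(isInh, sn$lifI$Vth, sn$lifE$Vth),
      sVres = ifelse(isInh, sn$lifI$Vres, sn$lifE$Vres),
      sTref = ifelse(isInh, sn$lifI$tref, sn$lifE$tref),
      sTauAmpa = sn$tauAmpa, sTauGaba = sn$tauGaba,
      senPtr = rec$ptr, senTgt = rec$tgt, senW = w / sc,
      xPtr = xc$ptr, xTgt = xc$tgt, xW = xw / sc,
      nX = sz$nX, rateX = sn$rateX)
  })
}

#' Build the integration circuit
#'
#' All-to-all connected attractor circuit (no self-connections): recurrent
#' efficacies within each selective population D1/D2 are scaled by w+ = 1.6,
#' connections from outside onto a selective population by the compensating
#' depression factor w- = 1 - f (w+ - 1)/(1 - f) with f the selective
#' fraction, conserving total recurrent excitation. Excitatory links carry
#' AMPA + NMDA, inhibitory links GABA_A.
#'
#' @param config a \code{NetworkConfig}.
#' @return A list of per-neuron parameters and block weights.
#' @export
buildIntegrationCircuit <- function(config) {
  p <- config@params; it <- p$integration; sz <- populationSizes(config)
  sc <- config@scale
  Ni <- sz$nD1 + sz$nD2 + sz$nDn + sz$nIi
  popI <- c(rep(0L, sz$nD1), rep(1L, sz$nD2), rep(2L, sz$nDn), rep(3L, sz$nIi))
  isI <- popI == 3L
  f <- sz$nD1 / (sz$nD1 + sz$nD2 + sz$nDn)
  wm <- wMinusIntegration(it$wPlus, f)
  wBlock <- rbind(
    c(it$wPlus, wm, wm),   # onto D1 from {D1, D2, Dn}
    c(wm, it$wPlus, wm),   # onto D2
    c(1, 1, 1),            # onto Dn
    c(1, 1, 1))            # onto I
  list(Ni = Ni, popI = popI,
    iCm = ifelse(isI, it$lifI$Cm, it$lifE$Cm),
    iGl = ifelse(isI, it$lifI$gL, it$lifE$gL),
    iEl = ifelse(isI, it$lifI$EL, it$lifE$EL),
    iVth = ifelse(isI, it$lifI$Vth, it$lifE$Vth),
    iVres = ifelse(isI, it$lifI$Vres, it$lifE$Vres),
    iTref = ifelse(isI, it$lifI$tref, it$lifE$tref),
    iTauAmpa = it$tauAmpa, iTauGaba = it$tauGaba,
    iTauNmda = it$tauNmda, iTauNmdaRise = it$tauNmdaRise,
    iAlphaNmda = it$alphaNmda,
    iBgRate = ifelse(popI <= 1L, it$bgRateD, it$bgRateN),
    iGext = ifelse(isI, it$gExtI, it$gExtE),
    iGrecAmpa = ifelse(isI, it$gAmpaI, it$gAmpaE) / sc,
    iGrecNmda = ifelse(isI, it$gNmdaI, it$gNmdaE) / sc,
    iGrecGaba = ifelse(isI, it$gGabaI, it$gGabaE) / sc,
    wBlock = wBlock, mg = p$common$mg)
}

#' Couple the sensory and integration circuits
#'
#' Topographic feedforward (E1 -> D1, E2 -> D2, probability pFF) and
#' feedback (D1 -> E1, D2 -> E2, probability pFB, efficacy 0.0668 nS x bFB)
#' pathways. bFB = 0 yields a purely feedforward hierarchy. With a
#' heterogeneity map, the per-target feedback factor multiplies the nominal
#' efficacy.
#'
#' @param config a \code{NetworkConfig}.
#' @param seed coupling seed.
#' @return A list with FF and FB CSR arrays.
#' @export
coupleCircuits <- function(config, seed) {
  cp <- config@params$coupling; sz <- populationSizes(config)
  sc <- config@scale
  Ns <- sz$nE1 + sz$nE2 + sz$nIs
  Ni <- sz$nD1 + sz$nD2 + sz$nDn + sz$nIi
  bFBfac <- rep(1, Ns)
  if (!is.null(config@heterogeneity)) bFBfac <- config@heterogeneity$bFBfac
  withSeed(deriveSeed(seed, "coupling"), {
    # feedforward: sensory E -> D; the E2 -> D2 block mirrors E1 -> D1 so
    # the coupling is exactly symmetric between the two pathways
    d1 <- 0:(sz$nD1 - 1L)
    ffT <- vector("list", Ns)
    for (i in seq_len(Ns)) ffT[[i]] <- integer(0)
    for (i in seq_len(sz$nE1)) {
      hit <- d1[runif(sz$nD1) < cp$pFF]
      ffT[[i]] <- hit
      ffT[[sz$nE1 + i]] <- hit + sz$nD1
    }
    ffPtr <- c(0L, cumsum(lengths(ffT)))
    ffTgt <- as.integer(unlist(ffT))
    # feedback: D -> sensory E, mirrored likewise
    e1 <- 0:(sz$nE1 - 1L)
    fbT <- vector("list", Ni)
    for (i in seq_len(Ni)) fbT[[i]] <- integer(0)
    for (i in seq_len(sz$nD1)) {
      hit <- e1[runif(sz$nE1) < cp$pFB]
      fbT[[i]] <- hit
      fbT[[sz$nD1 + i]] <- hit + sz$nE1
    }
    fbPtr <- c(0L, cumsum(lengths(fbT)))
    fbTgt <- as.integer(unlist(fbT))
    fbW <- cp$gFBbase * config@bFB * bFBfac[fbTgt + 1L] / sc
    list(ffPtr = ffPtr, ffTgt = ffTgt, ffW = rep(cp$gFF / sc, length(ffTgt)),
         fbPtr = fbPtr, fbTgt = fbTgt, fbW = fbW)
  })
}

#' Build the full hierarchical network
#'
#' @param config a \code{NetworkConfig}.
#' @param seed master connectivity seed; the realized network is a pure
#'   function of (config, seed).
#' @return A \code{Network}.
#' @export
#' @examples
#' net <- buildNetwork(networkConfig(scale = 0.05), seed = 1)
#' head(populations(net))
buildNetwork <- function(config, seed = 1) {
  validObject(config)
  sz <- populationSizes(config)
  sens <- buildSensoryCircuit(config, seed)
  intg <- buildIntegrationCircuit(config)
  coup <- coupleCircuits(config, seed)
  arrays <- c(sens, intg, coup,
    list(eAmpa = config@params$common$eAmpa, eGaba = config@params$common$eGaba))
  popNames <- c(rep("E1", sz$nE1), rep("E2", sz$nE2), rep("Is", sz$nIs),
                rep("D1", sz$nD1), rep("D2", sz$nD2), rep("Dn", sz$nDn),
                rep("Ii", sz$nIi))
  circuit <- c(rep("sensory", sens$Ns), rep("integration", intg$Ni))
  id <- c(0:(sens$Ns - 1L), 0:(intg$Ni - 1L))
  group <- rep(NA_character_, length(id))
  if (!is.null(config@heterogeneity))
    group[seq_len(sens$Ns)] <- config@heterogeneity$group
  pops <- data.frame(id = id, circuit = circuit, population = popNames,
                     group = group, stringsAsFactors = FALSE)
  new("Network", config = config, seed = seed, arrays = arrays,
      populations = pops)
}

#' Count realized directed links of a pathway
#'
#' For the sparse pathways (sensory recurrent, X, feedforward, feedback) the
#' realized CSR lists are counted; for the all-to-all integration circuit
#' the count is implied by the population sizes (no self-connections).
#'
#' @param network a \code{Network}.
#' @param from,to population names (E1, E2, Is, X, D1, D2, Dn, Ii).
#' @return Number of directed links from `from` to `to`.
#' @export
connectionCount <- function(network, from, to) {
  a <- network@arrays
  sz <- populationSizes(network@config)
  rng <- list(E1 = c(0, sz$nE1), E2 = c(sz$nE1, sz$nE1 + sz$nE2),
    Is = c(sz$nE1 + sz$nE2, a$Ns),
    D1 = c(0, sz$nD1), D2 = c(sz$nD1, sz$nD1 + sz$nD2),
    Dn = c(sz$nD1 + sz$nD2, sz$nD1 + sz$nD2 + sz$nDn),
    Ii = c(sz$nD1 + sz$nD2 + sz$nDn, a$Ni))
  inRange <- function(x, r) x >= r[1] & x < r[2]
  countCsr <- function(ptr, tgt, srcR, tgtR) {
    src <- rep(seq_along(diff(ptr)) - 1L, diff(ptr))
    sum(inRange(src, srcR) & inRange(tgt, tgtR))
  }
  sensPops <- c("E1", "E2", "Is"); intPops <- c("D1", "D2", "Dn", "Ii")
  if (from == "X") {
    stopifnot(to %in% sensPops)
    return(countCsr(a$xPtr, a$xTgt, c(0, a$nX), rng[[to]]))
  }
  if (from %in% sensPops && to %in% sensPops)
    return(countCsr(a$senPtr, a$senTgt, rng[[from]], rng[[to]]))
  if (from %in% sensPops && to %in% intPops)
    return(countCsr(a$ffPtr, a$ffTgt, rng[[from]], rng[[to]]))
  if (from %in% intPops && to %in% sensPops)
    return(countCsr(a$fbPtr, a$fbTgt, rng[[from]], rng[[to]]))
  # all-to-all integration circuit, no self-connections
  nFrom <- diff(rng[[from]]); nTo <- diff(rng[[to]])
  if (from == to) nFrom * (nTo - 1) else nFrom * nTo
}

#' Population table of a built network
#' @param network a \code{Network}.
#' @return data.frame with id (0-based, within circuit), circuit, population
#'   and heterogeneity group.
#' @export
populations <- function(network) network@populations

#' Independent homogeneous Poisson background spike trains
#'
#' @param rate rate per source, sp/s.
#' @param nSources number of sources.
#' @param duration duration, ms.
#' @param seed integer seed.
#' @return List of sorted spike-time vectors (ms), one per source.
#' @export
#' @examples
#' st <- poissonBackground(12.5, 10, 1000, seed = 1)
poissonBackground <- function(rate, nSources, duration, seed = 1) {
  if (rate < 0) stop("rate must be >= 0")
  withSeed(deriveSeed(seed, "poisson-background"), {
    lapply(seq_len(nSources), function(i) {
      n <- rpois(1, rate * duration / 1000)
      sort(runif(n, 0, duration))
    })
  })
}
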