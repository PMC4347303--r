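// Core event-driven/clock-driven simulator for the two-stage decision network.
//
// Sensory circuit: conductance-based LIF, AMPA + GABA_A exponential synapses,
// sparse random connectivity (CSR), external Poisson population X, injected
// stimulus currents, top-down AMPA feedback from the integration circuit.
//
// Integration circuit: conductance-based LIF with AMPA/NMDA/GABA_A kinetics
// and all-to-all block-structured connectivity, simulated with presynaptic
// gating variables and population sums (exact for uniform block weights).
//
// Forward Euler, dt = 0.1 ms; all spike effects delayed by a uniform
// transmission delay. Units internally: mV, ms, nS, pF, pA.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <random>

using namespace Rcpp;

// splitmix64: stable per-stream seed derivation (independent of R's RNG)
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline uint64_t streamSeed(uint64_t base, uint64_t role, uint64_t idx) {
  return splitmix64(splitmix64(base ^ (role * 0x9E3779B97F4A7C15ULL)) + idx);
}

// Exact-discretization OU update path, unit variance, zero mean.
// Shared by the stimulus generator and the simulator so that per-neuron
// stimulus streams are reconstructable from (seed, neuron index) alone.
static void ouFill(double* out, int n, double tau, double dt, uint64_t seed) {
  std::mt19937_64 rng(seed);
  std::normal_distribution<double> norm(0.0, 1.0);
  if (n <= 0) return;
  const double a = std::exp(-dt / tau);
  const double b = std::sqrt(1.0 - a * a);
  double x = norm(rng); // stationary start
  out[0] = x;
  for (int i = 1; i < n; ++i) {
    x = a * x + b * norm(rng);
    out[i] = x;
  }
}

// [[Rcpp::export(name = ".ouPathCpp")]]
NumericVector ouPathCpp(int n, double tau, double dt, double seed) {
  NumericVector out(n);
  if (n > 0) ouFill(REAL(out), n, tau, dt, (uint64_t)seed);
  return out;
}

// Per-neuron individual stimulus modulation path (1 ms resolution), stream
// derived from (stimulusSeed, neuron index) so it is stable under resizing.
// [[Rcpp::export(name = ".indOuPathCpp")]]
NumericVector indOuPathCpp(double stimSeed, int neuron, int n, double tau, double dt) {
  NumericVector out(n);
  if (n > 0) ouFill(REAL(out), n, tau, dt, streamSeed((uint64_t)stimSeed, 2u, (uint64_t)neuron));
  return out;
}

struct Csr {
  const int* ptr;
  const int* tgt;
  const double* w;
  bool ok;
};

static Csr getCsr(const List& net, const char* p, const char* t, const char* w) {
  Csr c;
  IntegerVector ptr = net[p];
  IntegerVector tgt = net[t];
  NumericVector wv = net[w];
  c.ptr = INTEGER(ptr); c.tgt = INTEGER(tgt); c.w = REAL(wv);
  c.ok = ptr.size() > 1;
  return c;
}

// [[Rcpp::export(name = ".simulateTrialCpp")]]
List simulateTrialCpp(List net, List stim, List run) {
  // ---- unpack run control ----
  const double dt = as<double>(run["dt"]);              // ms
  const double preMs = as<double>(run["preMs"]);
  const double stimMs = as<double>(run["stimMs"]);
  const int delaySteps = as<int>(run["delaySteps"]);
  const double bgSeed = as<double>(run["bgSeed"]);
  const double initSeed = as<double>(run["initSeed"]);
  const double recordFromMs = as<double>(run["recordFromMs"]);
  // optional direct Poisson-rate stimulation of the decision populations
  // (classical attractor-model protocol; diagnostics and calibration)
  const double boostD1 = run.containsElementNamed("bgBoostD1") ?
    as<double>(run["bgBoostD1"]) : 0.0;
  const double boostD2 = run.containsElementNamed("bgBoostD2") ?
    as<double>(run["bgBoostD2"]) : 0.0;
  LogicalVector recS = run["recordSensory"];            // per sensory neuron
  LogicalVector recI = run["recordIntegration"];        // per integration neuron
  IntegerVector vIds = run["voltageIds"];               // sensory ids, 0-based, 1 ms trace

  const int nSteps = (int)std::llround((preMs + stimMs) / dt);
  const int stepsPerMs = (int)std::llround(1.0 / dt);
  const int preSteps = (int)std::llround(preMs / dt);

  // ---- sensory circuit ----
  const int Ns = as<int>(net["Ns"]);
  IntegerVector popS_ = net["popS"]; // 0=E1,1=E2,2=I
  const int* popS = INTEGER(popS_);
  NumericVector sCm_ = net["sCm"], sGl_ = net["sGl"], sEl_ = net["sEl"],
    sVth_ = net["sVth"], sVres_ = net["sVres"], sTref_ = net["sTref"];
  const double *sCm = REAL(sCm_), *sGl = REAL(sGl_), *sEl = REAL(sEl_),
    *sVth = REAL(sVth_), *sVres = REAL(sVres_), *sTref = REAL(sTref_);
  const double tauAmpaS = as<double>(net["sTauAmpa"]);
  const double tauGabaS = as<double>(net["sTauGaba"]);
  const double eAmpa = as<double>(net["eAmpa"]);   // 0 mV
  const double eGaba = as<double>(net["eGaba"]);   // -70 mV
  Csr sen = getCsr(net, "senPtr", "senTgt", "senW");   // sensory -> sensory
  LogicalVector sInh = net["sIsInh"];
  Csr xc  = getCsr(net, "xPtr", "xTgt", "xW");         // X -> sensory
  Csr ff  = getCsr(net, "ffPtr", "ffTgt", "ffW");      // sensory E -> integration D
  Csr fb  = getCsr(net, "fbPtr", "fbTgt", "fbW");      // integration D -> sensory E
  const int nX = as<int>(net["nX"]);
  const double rateX = as<double>(net["rateX"]);       // sp/s per source

  // ---- integration circuit ----
  const int Ni = as<int>(net["Ni"]);
  IntegerVector popI_ = net["popI"]; // 0=D1,1=D2,2=Dn,3=I
  const int* popI = INTEGER(popI_);
  NumericVector iCm_ = net["iCm"], iGl_ = net["iGl"], iEl_ = net["iEl"],
    iVth_ = net["iVth"], iVres_ = net["iVres"], iTref_ = net["iTref"];
  const double *iCm = REAL(iCm_), *iGl = REAL(iGl_), *iEl = REAL(iEl_),
    *iVth = REAL(iVth_), *iVres = REAL(iVres_), *iTref = REAL(iTref_);
  const double tauAmpaI = as<double>(net["iTauAmpa"]);
  const double tauGabaI = as<double>(net["iTauGaba"]);
  const double tauNmda = as<double>(net["iTauNmda"]);
  const double tauX    = as<double>(net["iTauNmdaRise"]);
  const double alphaN  = as<double>(net["iAlphaNmda"]);  // 1/ms
  NumericVector bgRate_ = net["iBgRate"];                // sp/s aggregated per neuron
  NumericVector gExt_   = net["iGext"];                  // nS per background spike
  NumericVector gRecAmpa_ = net["iGrecAmpa"];            // per neuron (E vs I target)
  NumericVector gRecNmda_ = net["iGrecNmda"];
  NumericVector gRecGaba_ = net["iGrecGaba"];
  const double *bgRate = REAL(bgRate_), *gExt = REAL(gExt_),
    *gRecAmpa = REAL(gRecAmpa_), *gRecNmda = REAL(gRecNmda_),
    *gRecGaba = REAL(gRecGaba_);
  NumericMatrix wBlockM = net["wBlock"];                 // 4x3: target pop x {D1,D2,Dn}
  double wBlock[4][3];
  for (int p = 0; p < 4; ++p)
    for (int q = 0; q < 3; ++q) wBlock[p][q] = wBlockM(p, q);
  const double mgConc = as<double>(net["mg"]);

  // ---- stimulus ----
  const double I0 = as<double>(stim["I0"]) * 1000.0;     // nA -> pA
  NumericVector gammaC = stim["gammaC"];                 // per sensory neuron: gamma^beta * c
  NumericVector sigS = stim["sigmaStim"];                // per sensory neuron
  NumericVector sigI = stim["sigmaInd"];
  NumericVector zE1 = stim["zE1"];                       // unit OU per ms, length >= stimMs
  NumericVector zE2 = stim["zE2"];
  const double stimSeed = as<double>(stim["stimSeed"]);
  const double tauStim = as<double>(stim["tauStim"]);
  const int stimMsN = (int)std::llround(stimMs);
  if (stimMsN > 0 && (zE1.size() < stimMsN || zE2.size() < stimMsN))
    stop("common stimulus paths shorter than the stimulus epoch");

  // Pregenerate individual modulation paths (1 ms resolution) for sensory E
  // neurons that have sigmaInd > 0.
  std::vector<double> zInd;
  std::vector<int> zIndRow(Ns, -1);
  {
    int nrow = 0;
    for (int i = 0; i < Ns; ++i) if (sigI[i] > 0) zIndRow[i] = nrow++;
    if (nrow > 0 && stimMsN > 0) {
      zInd.resize((size_t)nrow * stimMsN);
      for (int i = 0; i < Ns; ++i) {
        if (zIndRow[i] >= 0)
          ouFill(&zInd[(size_t)zIndRow[i] * stimMsN], stimMsN, tauStim, 1.0,
                 streamSeed((uint64_t)stimSeed, 2u, (uint64_t)i));
      }
    }
  }

  // ---- RNGs ----
  std::mt19937_64 rngBg(streamSeed((uint64_t)bgSeed, 11u, 0u));
  std::mt19937_64 rngInit(streamSeed((uint64_t)initSeed, 13u, 0u));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const double pX = rateX * dt / 1000.0;
  std::binomial_distribution<int> binomX(nX, pX);
  std::uniform_int_distribution<int> pickX(0, nX > 0 ? nX - 1 : 0);
  std::exponential_distribution<double> expDist(1.0);

  // ---- state ----
  std::vector<double> vS(Ns), gAmpaS(Ns, 0.0), gGabaS(Ns, 0.0), refS(Ns, 0.0);
  std::vector<double> vI(Ni), gAmpaExtI(Ni, 0.0), refI(Ni, 0.0);
  std::vector<double> sAmpa(Ni, 0.0), xNmda(Ni, 0.0), sNmda(Ni, 0.0), sGaba(Ni, 0.0);
  for (int i = 0; i < Ns; ++i) vS[i] = sVres[i] + unif(rngInit) * (sVth[i] - sVres[i]);
  for (int i = 0; i < Ni; ++i) vI[i] = iVres[i] + unif(rngInit) * (iVth[i] - iVres[i]);

  // background arrival clocks (ms) for integration neurons
  std::vector<double> nextBg(Ni);
  for (int i = 0; i < Ni; ++i)
    nextBg[i] = (bgRate[i] > 0) ? expDist(rngBg) * 1000.0 / bgRate[i] : 1e300;
  std::vector<double> nextBoost(Ni, 1e300);

  // delay ring buffers
  const int D = delaySteps + 1;
  std::vector<double> ringAmpaS((size_t)D * Ns, 0.0), ringGabaS((size_t)D * Ns, 0.0);
  std::vector<double> ringExtI((size_t)D * Ni, 0.0);
  std::vector<std::vector<int>> ringSpkI(D); // integration spikes pending gating update

  // decay factors
  const double dAmpaS = std::exp(-dt / tauAmpaS), dGabaS = std::exp(-dt / tauGabaS);
  const double dAmpaI = std::exp(-dt / tauAmpaI), dGabaI = std::exp(-dt / tauGabaI);
  const double dXN = std::exp(-dt / tauX);

  // Mg-block lookup table: B(V) = 1/(1 + mg/3.57 * exp(-0.062 V)), V in mV
  const double vLo = -100.0, vHi = 20.0, vStep = 0.05;
  const int nTab = (int)((vHi - vLo) / vStep) + 2;
  std::vector<double> mgTab(nTab);
  for (int i = 0; i < nTab; ++i) {
    double v = vLo + i * vStep;
    mgTab[i] = 1.0 / (1.0 + mgConc / 3.57 * std::exp(-0.062 * v));
  }
  auto mgB = [&](double v) {
    if (v <= vLo) v = vLo;
    if (v >= vHi) v = vHi;
    int ix = (int)((v - vLo) / vStep);
    double fr = (v - vLo) / vStep - ix;
    return mgTab[ix] * (1 - fr) + mgTab[ix + 1] * fr;
  };

  // ---- output ----
  std::vector<int> spkIdS, spkIdI;
  std::vector<double> spkTS, spkTI;
  spkIdS.reserve(1 << 16); spkIdI.reserve(1 << 15);
  const int nV = vIds.size();
  const int nMsTot = (int)std::llround(preMs + stimMs);
  NumericMatrix vTrace(nV > 0 ? nMsTot : 0, nV);

  const double recFrom = recordFromMs;
  std::vector<char> recSv(Ns), recIv(Ni);
  for (int i = 0; i < Ns; ++i) recSv[i] = recS[i] ? 1 : 0;
  for (int i = 0; i < Ni; ++i) recIv[i] = recI[i] ? 1 : 0;

  // population sums of gating variables: {D1, D2, Dn} for AMPA/NMDA, I for GABA
  double sumAmpa[3] = {0, 0, 0}, sumNmda[3] = {0, 0, 0}, sumGaba = 0.0;

  int checkCounter = 0;
  for (int step = 0; step < nSteps; ++step) {
    const double t = step * dt;
    const int slot = step % D;
    const int msIx = step / stepsPerMs;
    const int stimIx = msIx - (int)std::llround(preMs); // ms index into stimulus
    const bool inStim = stimIx >= 0 && stimIx < stimMsN;

    // deliver delayed conductance increments
    {
      double* ra = &ringAmpaS[(size_t)slot * Ns];
      double* rg = &ringGabaS[(size_t)slot * Ns];
      for (int i = 0; i < Ns; ++i) {
        gAmpaS[i] = gAmpaS[i] * dAmpaS + ra[i];
        gGabaS[i] = gGabaS[i] * dGabaS + rg[i];
        ra[i] = 0.0; rg[i] = 0.0;
      }
      double* re = &ringExtI[(size_t)slot * Ni];
      for (int i = 0; i < Ni; ++i) {
        gAmpaExtI[i] = gAmpaExtI[i] * dAmpaI + re[i];
        re[i] = 0.0;
      }
      for (int id : ringSpkI[slot]) {
        if (popI[id] == 3) sGaba[id] += 1.0;
        else { sAmpa[id] += 1.0; xNmda[id] += 1.0; }
      }
      ringSpkI[slot].clear();
    }

    // external population X spikes -> delayed AMPA increments on sensory
    if (nX > 0 && pX > 0) {
      int nsp = binomX(rngBg);
      const int dslot = (step + delaySteps) % D;
      double* ra = &ringAmpaS[(size_t)dslot * Ns];
      for (int s = 0; s < nsp; ++s) {
        int src = pickX(rngBg);
        for (int e = xc.ptr[src]; e < xc.ptr[src + 1]; ++e) ra[xc.tgt[e]] += xc.w[e];
      }
    }

    // integration background Poisson (per-neuron aggregated rate)
    for (int i = 0; i < Ni; ++i) {
      while (nextBg[i] <= t) {
        gAmpaExtI[i] += gExt[i];
        nextBg[i] += expDist(rngBg) * 1000.0 / bgRate[i];
      }
    }
    if (inStim && (boostD1 > 0 || boostD2 > 0)) {
      for (int i = 0; i < Ni; ++i) {
        const double br = popI[i] == 0 ? boostD1 : (popI[i] == 1 ? boostD2 : 0.0);
        if (br <= 0) continue;
        if (nextBoost[i] > 1e200) nextBoost[i] = t + expDist(rngBg) * 1000.0 / br;
        while (nextBoost[i] <= t) {
          gAmpaExtI[i] += gExt[i];
          nextBoost[i] += expDist(rngBg) * 1000.0 / br;
        }
      }
    }

    // ---- update integration gating variables and population sums ----
    sumAmpa[0] = sumAmpa[1] = sumAmpa[2] = 0.0;
    sumNmda[0] = sumNmda[1] = sumNmda[2] = 0.0;
    sumGaba = 0.0;
    for (int i = 0; i < Ni; ++i) {
      const int p = popI[i];
      if (p == 3) {
        sGaba[i] *= dGabaI;
        sumGaba += sGaba[i];
      } else {
        sAmpa[i] *= dAmpaI;
        double xv = xNmda[i] * dXN;
        double sv = sNmda[i];
        sv += dt * (-sv / tauNmda + alphaN * xv * (1.0 - sv));
        if (sv > 1.0) sv = 1.0;
        xNmda[i] = xv; sNmda[i] = sv;
        sumAmpa[p] += sAmpa[i];
        sumNmda[p] += sv;
      }
    }

    // ---- integration membrane update ----
    {
      const int dslot = (step + delaySteps) % D;
      for (int i = 0; i < Ni; ++i) {
        if (refI[i] > 0) { refI[i] -= dt; vI[i] = iVres[i]; continue; }
        const int p = popI[i];
        double wa = 0.0, wn = 0.0;
        for (int q = 0; q < 3; ++q) {
          wa += wBlock[p][q] * sumAmpa[q];
          wn += wBlock[p][q] * sumNmda[q];
        }
        // no self-connections in the all-to-all circuit
        double gabaIn = sumGaba;
        if (p < 3) {
          wa -= wBlock[p][p] * sAmpa[i];
          wn -= wBlock[p][p] * sNmda[i];
        } else {
          gabaIn -= sGaba[i];
        }
        double v = vI[i];
        double I = iGl[i] * (iEl[i] - v)
          + gAmpaExtI[i] * (eAmpa - v)
          + gRecAmpa[i] * wa * (eAmpa - v)
          + gRecNmda[i] * wn * mgB(v) * (eAmpa - v)
          + gRecGaba[i] * gabaIn * (eGaba - v);
        v += dt * I / iCm[i];
        if (v >= iVth[i]) {
          v = iVres[i];
          refI[i] = iTref[i];
          ringSpkI[dslot].push_back(i);
          if (fb.ok) { // top-down feedback to sensory AMPA
            double* ra = &ringAmpaS[(size_t)dslot * Ns];
            for (int e = fb.ptr[i]; e < fb.ptr[i + 1]; ++e) ra[fb.tgt[e]] += fb.w[e];
          }
          if (recIv[i] && t >= recFrom) { spkIdI.push_back(i); spkTI.push_back(t); }
        }
        vI[i] = v;
      }
    }

    // ---- sensory membrane update ----
    {
      const int dslot = (step + delaySteps) % D;
      double* raS = &ringAmpaS[(size_t)dslot * Ns];
      double* rgS = &ringGabaS[(size_t)dslot * Ns];
      double* reI = &ringExtI[(size_t)dslot * Ni];
      const double z1 = inStim ? zE1[stimIx] : 0.0;
      const double z2 = inStim ? zE2[stimIx] : 0.0;
      for (int i = 0; i < Ns; ++i) {
        if (refS[i] > 0) { refS[i] -= dt; vS[i] = sVres[i]; continue; }
        double v = vS[i];
        double I = sGl[i] * (sEl[i] - v)
          + gAmpaS[i] * (eAmpa - v)
          + gGabaS[i] * (eGaba - v);
        if (inStim && popS[i] < 2) {
          const double zc = (popS[i] == 0) ? z1 : z2;
          double zi = 0.0;
          if (zIndRow[i] >= 0) zi = zInd[(size_t)zIndRow[i] * stimMsN + stimIx];
          I += I0 * (1.0 + gammaC[i] + sigS[i] * zc + sigI[i] * zi);
        }
        v += dt * I / sCm[i];
        if (v >= sVth[i]) {
          v = sVres[i];
          refS[i] = sTref[i];
          if (sInh[i]) {
            for (int e = sen.ptr[i]; e < sen.ptr[i + 1]; ++e) rgS[sen.tgt[e]] += sen.w[e];
          } else {
            for (int e = sen.ptr[i]; e < sen.ptr[i + 1]; ++e) raS[sen.tgt[e]] += sen.w[e];
            if (ff.ok)
              for (int e = ff.ptr[i]; e < ff.ptr[i + 1]; ++e) reI[ff.tgt[e]] += ff.w[e];
          }
          if (recSv[i] && t >= recFrom) { spkIdS.push_back(i); spkTS.push_back(t); }
        }
        vS[i] = v;
      }
    }

    // voltage traces at 1 ms resolution (record at first sub-step of each ms)
    if (nV > 0 && step % stepsPerMs == 0) {
      for (int j = 0; j < nV; ++j) vTrace(msIx, j) = vS[vIds[j]];
    }

    if (++checkCounter >= 2000) {
      checkCounter = 0;
      for (int i = 0; i < Ns; ++i)
        if (!std::isfinite(vS[i]))
          stop("numerical divergence: sensory neuron %d at t = %.1f ms", i + 1, t);
      for (int i = 0; i < Ni; ++i)
        if (!std::isfinite(vI[i]))
          stop("numerical divergence: integration neuron %d at t = %.1f ms", i + 1, t);
      Rcpp::checkUserInterrupt();
    }
  }

  (void)preSteps;
  return List::create(
    _["sensId"] = wrap(spkIdS), _["sensT"] = wrap(spkTS),
    _["intId"] = wrap(spkIdI), _["intT"] = wrap(spkTI),
    _["vTrace"] = vTrace);
}
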