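// Adaptive random-walk Metropolis-within-Gibbs sampler for the
// hierarchical roost-count state-space model.
//
// Parameters are updated one at a time by random walks on
// interval-logit-transformed scales (so proposals respect the prior
// boxes) against the collapsed likelihood (in-camp states integrated
// out); the log total-population path is then drawn exactly from its
// Gaussian full conditional (tridiagonal precision), and the log
// in-camp states are refreshed from their conjugate conditionals. A
// joint level move handles the near-flat scale direction between the
// seasonal availability level and the population level. Proposal
// scales adapt toward target acceptance rates during burn-in only and
// are frozen afterwards.
//
// All randomness comes from R's RNG, so results are reproducible via
// set.seed() on the calling side.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const int NPAR = 10;
// order: rho, mu, cRho, cMu, cR, alpha1, alpha2, sigmaProc, sigmaCamp, sigmaObs
enum { RHO = 0, MU, CRHO, CMU, CR, A1, A2, SPROC, SCAMP, SOBS };

// The seasonality pair (alpha1, alpha2) is sampled through the December
// proportion pDec = (alpha1 + 1)/alpha2 and the June/December ratio
// q = pJun/pDec = (alpha1 - 1)/(alpha1 + 1), both in (0, 1): the model
// constraints alpha1 > 1, alpha2 > alpha1 + 1 map exactly onto the unit
// square, and both coordinates are directly identified by the data
// (alpha1 = (1 + q)/(1 - q), alpha2 = 2/(pDec (1 - q))). This removes
// the alpha1/alpha2 likelihood ridge that defeats coordinate-wise
// random walks on the natural scale.
struct Boxes {
  double lo[NPAR], hi[NPAR];
  explicit Boxes(double alphaMax) {
    (void)alphaMax;  // alpha truncation handled by the prior
    lo[RHO] = 0.0;    hi[RHO] = 0.11;
    lo[MU] = 0.0;     hi[MU] = 0.1;
    lo[CRHO] = 0.0;   hi[CRHO] = 1.0;
    lo[CMU] = 1.0;    hi[CMU] = 10.0;
    lo[CR] = 0.0;     hi[CR] = 1.0;
    lo[A1] = 0.0;     hi[A1] = 1.0;  // pDec
    lo[A2] = 0.0;     hi[A2] = 1.0;  // q = pJun/pDec
    lo[SPROC] = 0.0;  hi[SPROC] = 10.0;
    lo[SCAMP] = 0.0;  hi[SCAMP] = 100.0;
    lo[SOBS] = 0.05;  hi[SOBS] = 0.47;
  }
};

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

static inline double logitIn(double x, double lo, double hi) {
  double s = (x - lo) / (hi - lo);
  return std::log(s) - std::log1p(-s);
}

// natural parameter vector from transformed z
static void zToParams(const std::vector<double>& z, const Boxes& B,
                      std::vector<double>& p) {
  for (int j = 0; j < NPAR; ++j) {
    double s = sigmoid(z[j]);
    p[j] = B.lo[j] + (B.hi[j] - B.lo[j]) * s;
  }
  double pDec = p[A1], q = p[A2];
  p[A1] = (1.0 + q) / (1.0 - q);
  p[A2] = 2.0 / (pDec * (1.0 - q));
}

// log |d(natural)/dz|; the (alpha1, alpha2) block contributes the
// (pDec, q) -> (alpha1, alpha2) factor 4 / (pDec^2 (1 - q)^3) on top of
// the two unit-interval logit factors.
static double jacobian(const std::vector<double>& z, const Boxes& B) {
  double j = 0.0;
  for (int k = 0; k < NPAR; ++k) {
    double s = sigmoid(z[k]);
    j += std::log(B.hi[k] - B.lo[k]) + std::log(s) + std::log1p(-s);
  }
  double pDec = sigmoid(z[A1]), q = sigmoid(z[A2]);
  j += std::log(4.0) - 2.0 * std::log(pDec) - 3.0 * std::log1p(-q);
  return j;
}

static double logPriorC(const std::vector<double>& p, double alphaMax) {
  if (p[RHO] <= 0 || p[RHO] >= 0.11 || p[MU] <= 0 || p[MU] >= 0.1 ||
      p[CMU] <= 1 || p[CMU] >= 10 || p[CRHO] <= 0 || p[CRHO] >= 1 ||
      p[CR] <= 0 || p[CR] >= 1 || p[SOBS] <= 0.05 || p[SOBS] >= 0.47 ||
      p[SPROC] <= 0 || p[SPROC] >= 10 ||
      p[A1] <= 1 || p[A1] >= alphaMax ||
      p[A2] <= p[A1] + 1 || p[A2] >= alphaMax + 1 ||
      p[SCAMP] <= 0 || p[SCAMP] >= 100)
    return R_NegInf;
  double lp = 0.0;
  lp += -std::log(0.11) - std::log(0.1) - std::log(9.0);
  lp += R::dbeta(p[CRHO], 1.01, 1.01, 1);
  lp += -std::log(0.42) - std::log(10.0);
  lp += -std::log(alphaMax - 1.0);
  lp += -std::log(alphaMax - p[A1]);  // alpha2 | alpha1 ~ U(alpha1+1, alphaMax+1)
  lp += R::dbeta(p[CR], 1.01, 1.01, 1);
  lp += -std::log(100.0);
  return lp;
}

struct ModelData {
  int n;
  std::vector<double> logy, cosval, ramp;
  std::vector<int> obs, breed, pen;
  double x0Mean; // initial-state prior centre on the log scale
  double x0Sd;   // initial-state prior SD on the log scale
};

// seasonal proportion (log) and net growth rate per month for params p
static void derivedSeries(const std::vector<double>& p, const ModelData& D,
                          std::vector<double>& logp, std::vector<double>& g) {
  for (int t = 0; t < D.n; ++t) {
    logp[t] = std::log(D.cosval[t] + p[A1]) - std::log(p[A2]) +
              std::log1p(-p[CR] * D.ramp[t]);
    double rho_t = p[RHO] * D.breed[t] * (D.pen[t] ? p[CRHO] : 1.0);
    double mu_t = p[MU] * (1.0 + (p[CMU] - 1.0) * D.ramp[t]);
    g[t] = rho_t - mu_t;
  }
}

static inline double dnorm_log(double x, double m, double s) {
  double z = (x - m) / s;
  return -0.5 * z * z - std::log(s) - 0.9189385332046727;
}

// full likelihood of the log-scale states given derived series
static double likeAll(const ModelData& D, const std::vector<double>& p,
                      const std::vector<double>& logp,
                      const std::vector<double>& g,
                      const std::vector<double>& lx,
                      const std::vector<double>& lxc) {
  double ll = dnorm_log(lx[0], D.x0Mean, D.x0Sd);
  for (int t = 1; t < D.n; ++t)
    ll += dnorm_log(lx[t], lx[t - 1] + g[t], p[SPROC]);
  for (int t = 0; t < D.n; ++t) {
    ll += dnorm_log(lxc[t], logp[t] + lx[t], p[SCAMP]);
    if (D.obs[t]) ll += dnorm_log(D.logy[t], lxc[t], p[SOBS]);
  }
  return ll;
}

// collapsed likelihood with the in-camp states integrated out: the
// in-camp layer has no dynamics of its own, so marginally each
// observed count satisfies
//   log y_t ~ N(log p_t + log X_t, sigma_camp^2 + sigma_obs^2).
// Parameter and X-path updates target this marginal (much better
// mixing along the sigma_camp/sigma_obs trade-off); the in-camp states
// are then refreshed from their exact conditional.
static double likeMarg(const ModelData& D, const std::vector<double>& p,
                       const std::vector<double>& logp,
                       const std::vector<double>& g,
                       const std::vector<double>& lx) {
  double sm = std::sqrt(p[SCAMP] * p[SCAMP] + p[SOBS] * p[SOBS]);
  double ll = dnorm_log(lx[0], D.x0Mean, D.x0Sd);
  for (int t = 1; t < D.n; ++t)
    ll += dnorm_log(lx[t], lx[t - 1] + g[t], p[SPROC]);
  for (int t = 0; t < D.n; ++t)
    if (D.obs[t]) ll += dnorm_log(D.logy[t], logp[t] + lx[t], sm);
  return ll;
}

// [[Rcpp::export(name = ".runChain")]]
List runChain(NumericVector initParams, NumericVector initLogX,
              NumericVector initLogXC, NumericVector logy,
              IntegerVector obs, NumericVector cosval, NumericVector ramp,
              IntegerVector breed, IntegerVector pen, double x0Mean,
              double x0Sd, int nIter, int nBurnin, int thinStates,
              double alphaMax, bool priorOnly) {
  RNGScope scope;
  Boxes B(alphaMax);
  ModelData D;
  D.n = logy.size();
  D.logy = as<std::vector<double> >(logy);
  D.cosval = as<std::vector<double> >(cosval);
  D.ramp = as<std::vector<double> >(ramp);
  D.obs = as<std::vector<int> >(obs);
  D.breed = as<std::vector<int> >(breed);
  D.pen = as<std::vector<int> >(pen);
  D.x0Mean = x0Mean;
  D.x0Sd = x0Sd;

  std::vector<double> z(NPAR), p(NPAR);
  for (int j = 0; j < NPAR; ++j) p[j] = initParams[j];
  for (int j = 0; j < NPAR; ++j) {
    double x = p[j];
    if (j == A1) x = (p[A1] + 1.0) / p[A2];          // pDec
    else if (j == A2) x = (p[A1] - 1.0) / (p[A1] + 1.0);  // q
    z[j] = logitIn(x, B.lo[j], B.hi[j]);
  }
  std::vector<double> lx = as<std::vector<double> >(initLogX);
  std::vector<double> lxc = as<std::vector<double> >(initLogXC);
  std::vector<double> logp(D.n), g(D.n);
  derivedSeries(p, D, logp, g);

  double curPrior = logPriorC(p, alphaMax);
  double curLike = priorOnly ? 0.0 : likeMarg(D, p, logp, g, lx);
  double curJac = jacobian(z, B);
  if (!R_finite(curPrior) || !R_finite(curLike))
    stop("non-finite log joint density at initialization");

  // proposal scales (log) and adaptation bookkeeping
  std::vector<double> ls(NPAR, std::log(0.5));
  double lsLev = std::log(0.5);
  std::vector<int> batchAcc(NPAR, 0), batchTry(NPAR, 0);
  int batchAccLev = 0, batchTryLev = 0;
  std::vector<long> totAcc(NPAR, 0), totTry(NPAR, 0);
  long totAccLev = 0, totTryLev = 0;
  bool anyStateDraw = false;  // exact Gibbs draws: accepted by construction
  const int batchLen = 50;
  int batchNum = 0;

  int nStateKeep = priorOnly ? 0 : nIter / thinStates;
  NumericMatrix outPar(nIter, NPAR);
  NumericMatrix outX(nStateKeep, priorOnly ? 0 : D.n);
  NumericMatrix outXC(nStateKeep, priorOnly ? 0 : D.n);
  int stateRow = 0;

  int nTotal = nBurnin + nIter;
  std::vector<double> zProp(NPAR), pProp(NPAR);
  std::vector<double> logpProp(D.n), gProp(D.n);
  std::vector<double> lxProp(D.n);
  std::vector<double> diagBuf(D.n), offBuf(D.n), linBuf(D.n);
  std::vector<double> cholBuf(D.n), upBuf(D.n), wBuf(D.n);

  for (int it = 0; it < nTotal; ++it) {
    bool adapting = it < nBurnin;

    // --- scalar parameter updates ---
    for (int j = 0; j < NPAR; ++j) {
      zProp = z;
      zProp[j] = z[j] + std::exp(ls[j]) * R::norm_rand();
      zToParams(zProp, B, pProp);
      double prPrior = logPriorC(pProp, alphaMax);
      double prLike = 0.0;
      bool ok = R_finite(prPrior);
      if (ok && !priorOnly) {
        derivedSeries(pProp, D, logpProp, gProp);
        prLike = likeMarg(D, pProp, logpProp, gProp, lx);
        ok = R_finite(prLike);
      }
      if (ok) {
        double prJac = jacobian(zProp, B);
        double logA = (prPrior + prLike + prJac) -
                      (curPrior + curLike + curJac);
        if (std::log(R::unif_rand()) < logA) {
          z = zProp; p = pProp;
          curPrior = prPrior; curLike = prLike; curJac = prJac;
          if (!priorOnly) { logp = logpProp; g = gProp; }
          ++batchAcc[j]; if (!adapting) ++totAcc[j];
        }
      }
      ++batchTry[j]; if (!adapting) ++totTry[j];
    }

    if (!priorOnly) {
      // --- joint level move: pDec scales the availability curve
      // uniformly across months, so (log pDec += delta, logX -= delta)
      // leaves the camp and observation terms unchanged and is resisted
      // only by the initial-state term and prior; sampling this
      // direction jointly decouples the seasonality level from the
      // population level ---
      {
        double delta = std::exp(lsLev) * R::norm_rand();
        double pDec = sigmoid(z[A1]);
        double pDecNew = pDec * std::exp(delta);
        if (pDecNew < 1.0) {
          zProp = z;
          zProp[A1] = logitIn(pDecNew, 0.0, 1.0);
          zToParams(zProp, B, pProp);
          double prPrior = logPriorC(pProp, alphaMax);
          if (R_finite(prPrior)) {
            for (int t = 0; t < D.n; ++t) lxProp[t] = lx[t] - delta;
            derivedSeries(pProp, D, logpProp, gProp);
            double prLike = likeMarg(D, pProp, logpProp, gProp, lxProp);
            double prJac = jacobian(zProp, B);
            double logA = (prPrior + prLike + prJac) -
                          (curPrior + curLike + curJac) +
                          std::log1p(-pDec) - std::log1p(-pDecNew);
            if (R_finite(prLike) && std::log(R::unif_rand()) < logA) {
              z = zProp; p = pProp; lx.swap(lxProp);
              curPrior = prPrior; curLike = prLike; curJac = prJac;
              logp = logpProp; g = gProp;
              ++batchAccLev; if (!adapting) ++totAccLev;
            }
          }
        }
        ++batchTryLev; if (!adapting) ++totTryLev;
      }

      // --- exact Gibbs draw of the log total-population path ---
      // Given the parameters and log in-camp states, the log totals are
      // jointly Gaussian with a tridiagonal precision matrix (initial
      // term, process terms, camp terms); sample the whole path from
      // its full conditional by tridiagonal Cholesky.
      {
        double ip = 1.0 / (p[SPROC] * p[SPROC]);  // process precision
        double ic = 1.0 / (p[SCAMP] * p[SCAMP]);  // camp precision
        int n = D.n;
        std::vector<double>& dg = diagBuf; std::vector<double>& off = offBuf;
        std::vector<double>& L = linBuf;
        for (int t = 0; t < n; ++t) {
          dg[t] = ic + ip * ((t >= 1 ? 1 : 0) + (t <= n - 2 ? 1 : 0));
          L[t] = ic * (lxc[t] - logp[t]);
        }
        double i0 = 1.0 / (D.x0Sd * D.x0Sd);  // initial-state precision
        dg[0] += i0;
        L[0] += i0 * D.x0Mean;
        for (int t = 1; t < n; ++t) {
          // process term t couples x_t and x_{t-1} with offset g_t
          L[t] += ip * g[t];
          L[t - 1] -= ip * g[t];
          off[t - 1] = -ip;
        }
        // Cholesky Q = R^T R with R upper bidiagonal
        std::vector<double>& cd = cholBuf; std::vector<double>& cu = upBuf;
        cd[0] = std::sqrt(dg[0]);
        for (int t = 1; t < n; ++t) {
          cu[t - 1] = off[t - 1] / cd[t - 1];
          cd[t] = std::sqrt(dg[t] - cu[t - 1] * cu[t - 1]);
        }
        // solve R^T w = L forward, then R x = w + z backward
        std::vector<double>& w = wBuf;
        w[0] = L[0] / cd[0];
        for (int t = 1; t < n; ++t)
          w[t] = (L[t] - cu[t - 1] * w[t - 1]) / cd[t];
        for (int t = 0; t < n; ++t) w[t] += R::norm_rand();
        lx[n - 1] = w[n - 1] / cd[n - 1];
        for (int t = n - 2; t >= 0; --t)
          lx[t] = (w[t] - cu[t] * lx[t + 1]) / cd[t];
        anyStateDraw = true;
      }

      // --- exact Gibbs draw of the log in-camp states ---
      // Each log in-camp state has a conjugate normal full conditional
      // combining its camp term and (when surveyed) observation term.
      {
        double ic = 1.0 / (p[SCAMP] * p[SCAMP]);
        double io = 1.0 / (p[SOBS] * p[SOBS]);
        for (int t = 0; t < D.n; ++t) {
          double prec = ic + (D.obs[t] ? io : 0.0);
          double mean = (ic * (logp[t] + lx[t]) +
                         (D.obs[t] ? io * D.logy[t] : 0.0)) / prec;
          lxc[t] = mean + R::norm_rand() / std::sqrt(prec);
        }
      }
      curLike = likeMarg(D, p, logp, g, lx);
    }

    // --- adaptation (burn-in only) ---
    if (adapting && (it + 1) % batchLen == 0) {
      ++batchNum;
      double delta = std::min(0.05, 1.0 / std::sqrt((double)batchNum));
      for (int j = 0; j < NPAR; ++j) {
        double rate = batchTry[j] ? (double)batchAcc[j] / batchTry[j] : 0.0;
        ls[j] += (rate > 0.44 ? delta : -delta);
        batchAcc[j] = batchTry[j] = 0;
      }
      if (batchTryLev) {
        double rate = (double)batchAccLev / batchTryLev;
        lsLev += (rate > 0.44 ? delta : -delta);
        batchAccLev = batchTryLev = 0;
      }
    }

    // --- storage ---
    if (it >= nBurnin) {
      int k = it - nBurnin;
      for (int j = 0; j < NPAR; ++j) outPar(k, j) = p[j];
      if (!priorOnly && (k + 1) % thinStates == 0 && stateRow < nStateKeep) {
        for (int t = 0; t < D.n; ++t) {
          outX(stateRow, t) = lx[t];
          outXC(stateRow, t) = lxc[t];
        }
        ++stateRow;
      }
    }
  }

  NumericVector accPar(NPAR);
  for (int j = 0; j < NPAR; ++j)
    accPar[j] = totTry[j] ? (double)totAcc[j] / totTry[j] : NA_REAL;
  double accState = anyStateDraw ? 1.0 : NA_REAL;
  double accLev = totTryLev ? (double)totAccLev / totTryLev : NA_REAL;

  return List::create(_["params"] = outPar, _["logX"] = outX,
                      _["logXC"] = outXC, _["accParams"] = accPar,
                      _["accX"] = accState, _["accXC"] = accState,
                      _["accLevel"] = accLev);
}

// log joint over log-scale states (normal-density form), used to
// cross-check the sampler's internal density against the R-level
// log-normal decomposition (they differ by the log-state Jacobian).
// [[Rcpp::export(name = ".logTargetCpp")]]
double logTargetCpp(NumericVector paramsVec, NumericVector logX,
                    NumericVector logXC, NumericVector logy,
                    IntegerVector obs, NumericVector cosval,
                    NumericVector ramp, IntegerVector breed,
                    IntegerVector pen, double x0Mean, double x0Sd,
                    double alphaMax) {
  ModelData D;
  D.n = logy.size();
  D.logy = as<std::vector<double> >(logy);
  D.cosval = as<std::vector<double> >(cosval);
  D.ramp = as<std::vector<double> >(ramp);
  D.obs = as<std::vector<int> >(obs);
  D.breed = as<std::vector<int> >(breed);
  D.pen = as<std::vector<int> >(pen);
  D.x0Mean = x0Mean;
  D.x0Sd = x0Sd;
  std::vector<double> p = as<std::vector<double> >(paramsVec);
  double lp = logPriorC(p, alphaMax);
  if (!R_finite(lp)) return R_NegInf;
  std::vector<double> logp(D.n), g(D.n);
  derivedSeries(p, D, logp, g);
  std::vector<double> lx = as<std::vector<double> >(logX);
  std::vector<double> lxc = as<std::vector<double> >(logXC);
  return lp + likeAll(D, p, logp, g, lx, lxc);
}
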