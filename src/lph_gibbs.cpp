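// Collapsed Gibbs sampler for the pair-aware supervised topic model.
//
// Sampling units are either a single herb token or a mined herb pair
// (both member herbs share one function assignment). Assignments are
// restricted to each prescription's active label set. Conditional
// weights follow the collapsed-LDA algebra with symmetric priors:
//
//   singleton:  (n_kh[h]+eta) / (n_k+eta*V) * (n_pk+alpha) / (n_p-1+alpha*Kp)
//   pair:       (n_kh[h1]+eta)(n_kh[h2]+eta) / (n_k+eta*V)
//                 * (n_pk+alpha) / (n_p-2+alpha*Kp)
//
// with all counts excluding the unit being resampled. The pair form uses
// the shared (n_k + eta*V) denominator exactly once. Weights are
// computed in log space and exponentiated after a max-shift. All
// randomness comes from R's RNG (unif_rand), so set.seed() in R fixes
// the trajectory bit-for-bit.

#include <Rcpp.h>
using namespace Rcpp;

static inline void unit_log_weights(
    const IntegerMatrix& nkh, const IntegerVector& nk,
    const IntegerMatrix& npk, int npExcl,
    int h1, int h2, int p, const IntegerVector& active,
    double alpha, double eta, int V, std::vector<double>& lw) {
  const int Kp = active.size();
  const double docDen = std::log(npExcl + alpha * Kp);
  for (int a = 0; a < Kp; ++a) {
    const int k = active[a];
    double w = std::log(nkh(k, h1) + eta);
    if (h2 >= 0) w += std::log(nkh(k, h2) + eta);
    w -= std::log(nk[k] + eta * V);
    w += std::log(npk(p, k) + alpha) - docDen;
    lw[a] = w;
  }
}

// Normalized conditional distribution over a prescription's active
// labels for one unit, given counts that already exclude the unit.
// [[Rcpp::export]]
NumericVector cpp_unit_conditional(IntegerMatrix nkh, IntegerVector nk,
                                   IntegerMatrix npk, int npExcl,
                                   int h1, int h2, int p,
                                   IntegerVector active,
                                   double alpha, double eta, int V) {
  std::vector<double> lw(active.size());
  unit_log_weights(nkh, nk, npk, npExcl, h1, h2, p, active,
                   alpha, eta, V, lw);
  double mx = *std::max_element(lw.begin(), lw.end());
  NumericVector out(active.size());
  double tot = 0.0;
  for (int a = 0; a < (int)lw.size(); ++a) {
    out[a] = std::exp(lw[a] - mx);
    tot += out[a];
  }
  for (int a = 0; a < (int)lw.size(); ++a) out[a] /= tot;
  return out;
}

// Run nIter full Gibbs sweeps from the assignment vector z.
// unitH1/unitH2: 0-based herb ids (unitH2 = -1 for singletons);
// unitPres: 0-based prescription index; z: 0-based label assignment;
// activeLabels: per-prescription 0-based active label sets.
// avgS > 0 averages beta/theta over the last avgS sweeps;
// traceLast > 0 records pair-unit assignments for the last sweeps.
// [[Rcpp::export]]
List cpp_lph_gibbs(IntegerVector unitH1, IntegerVector unitH2,
                   IntegerVector unitPres, IntegerVector z,
                   List activeLabels, int K, int V, int P,
                   double alpha, double eta, int nIter,
                   int avgS, int traceLast) {
  const int U = unitH1.size();
  IntegerMatrix nkh(K, V);
  IntegerVector nk(K);
  IntegerMatrix npk(P, K);
  IntegerVector np(P);
  std::vector<IntegerVector> act(P);
  for (int p = 0; p < P; ++p) act[p] = activeLabels[p];

  IntegerVector zc = clone(z);
  for (int u = 0; u < U; ++u) {
    const int k = zc[u], p = unitPres[u];
    const int size = (unitH2[u] >= 0) ? 2 : 1;
    nkh(k, unitH1[u])++;
    if (unitH2[u] >= 0) nkh(k, unitH2[u])++;
    nk[k] += size;
    npk(p, k) += size;
    np[p] += size;
  }

  std::vector<int> pairUnits;
  for (int u = 0; u < U; ++u) if (unitH2[u] >= 0) pairUnits.push_back(u);
  const int nTrace = std::min(traceLast, nIter);
  IntegerMatrix trace(traceLast > 0 ? nTrace : 0,
                      traceLast > 0 ? (int)pairUnits.size() : 0);

  NumericMatrix betaSum(avgS > 0 ? K : 0, avgS > 0 ? V : 0);
  NumericMatrix thetaSum(avgS > 0 ? P : 0, avgS > 0 ? K : 0);
  int nAvg = 0;

  std::vector<double> lw(K), w(K);
  RNGScope scope;

  for (int it = 1; it <= nIter; ++it) {
    for (int u = 0; u < U; ++u) {
      const int p = unitPres[u];
      const IntegerVector& A = act[p];
      const int Kp = A.size();
      const int h1 = unitH1[u], h2 = unitH2[u];
      const int size = (h2 >= 0) ? 2 : 1;
      const int kOld = zc[u];

      nkh(kOld, h1)--;
      if (h2 >= 0) nkh(kOld, h2)--;
      nk[kOld] -= size;
      npk(p, kOld) -= size;

      unit_log_weights(nkh, nk, npk, np[p] - size, h1, h2, p, A,
                       alpha, eta, V, lw);
      double mx = lw[0];
      for (int a = 1; a < Kp; ++a) if (lw[a] > mx) mx = lw[a];
      double tot = 0.0;
      for (int a = 0; a < Kp; ++a) { w[a] = std::exp(lw[a] - mx); tot += w[a]; }

      double r = unif_rand() * tot;
      int pick = Kp - 1;
      double acc = 0.0;
      for (int a = 0; a < Kp; ++a) {
        acc += w[a];
        if (r <= acc) { pick = a; break; }
      }
      const int kNew = A[pick];
      zc[u] = kNew;
      nkh(kNew, h1)++;
      if (h2 >= 0) nkh(kNew, h2)++;
      nk[kNew] += size;
      npk(p, kNew) += size;
    }

    if (avgS > 0 && it > nIter - avgS) {
      ++nAvg;
      for (int k = 0; k < K; ++k) {
        const double den = nk[k] + eta * V;
        for (int v = 0; v < V; ++v)
          betaSum(k, v) += (nkh(k, v) + eta) / den;
      }
      for (int p = 0; p < P; ++p) {
        const int Kp = act[p].size();
        const double den = np[p] + alpha * Kp;
        for (int a = 0; a < Kp; ++a) {
          const int k = act[p][a];
          thetaSum(p, k) += (npk(p, k) + alpha) / den;
        }
      }
    }
    if (traceLast > 0 && it > nIter - nTrace) {
      const int row = it - (nIter - nTrace) - 1;
      for (int j = 0; j < (int)pairUnits.size(); ++j)
        trace(row, j) = zc[pairUnits[j]];
    }
  }

  if (avgS > 0 && nAvg > 0) {
    for (int k = 0; k < K; ++k)
      for (int v = 0; v < V; ++v) betaSum(k, v) /= nAvg;
    for (int p = 0; p < P; ++p)
      for (int k = 0; k < K; ++k) thetaSum(p, k) /= nAvg;
  }

  return List::create(_["z"] = zc, _["nkh"] = nkh, _["nk"] = nk,
                      _["npk"] = npk, _["np"] = np,
                      _["betaAvg"] = betaSum, _["thetaAvg"] = thetaSum,
                      _["pairTrace"] = trace,
                      _["pairUnits"] = wrap(pairUnits));
}
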