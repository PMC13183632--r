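// Compiled core of the contrastive terms: per-anchor log-sum-exp ratios over
// positive / denominator mask matrices, with the optional gradient dL/dS.
// Numerically shifted per row by the max over admitted entries. All loops
// sweep columns (column-major storage) with per-row accumulators.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".contrastive_core")]]
List contrastive_core(NumericMatrix S, LogicalMatrix P, LogicalMatrix D,
                      double tau, bool want_grad) {
  const int n = S.nrow();
  const int N = S.ncol();
  const double *sv = &S[0];
  const int *pv = &P[0];
  const int *dv = &D[0];

  std::vector<double> mx(n, R_NegInf);
  std::vector<char> hasp(n, 0), hasd(n, 0);
  for (int k = 0; k < N; ++k) {
    const int off = k * n;
    for (int i = 0; i < n; ++i) {
      const bool p = pv[off + i] != 0, d = dv[off + i] != 0;
      if (p) hasp[i] = 1;
      if (d) hasd[i] = 1;
      if (p || d) {
        const double v = sv[off + i] / tau;
        if (v > mx[i]) mx[i] = v;
      }
    }
  }

  std::vector<char> contrib(n, 0);
  int n_used = 0;
  for (int i = 0; i < n; ++i) {
    if (hasp[i] && hasd[i]) { contrib[i] = 1; ++n_used; }
  }

  NumericMatrix g;
  std::vector<double> ebuf;
  if (want_grad) {
    g = NumericMatrix(n, N);
    ebuf.assign(static_cast<size_t>(n) * N, 0.0);
  }
  std::vector<double> sp(n, 0.0), sd(n, 0.0);
  for (int k = 0; k < N; ++k) {
    const int off = k * n;
    for (int i = 0; i < n; ++i) {
      if (!contrib[i]) continue;
      const bool p = pv[off + i] != 0, d = dv[off + i] != 0;
      if (p || d) {
        const double e = std::exp(sv[off + i] / tau - mx[i]);
        if (want_grad) ebuf[off + i] = e;
        if (p) sp[i] += e;
        if (d) sd[i] += e;
      }
    }
  }

  double value = 0.0;
  IntegerVector anchors(n_used);
  int a = 0;
  for (int i = 0; i < n; ++i) {
    if (contrib[i]) {
      value += std::log(sd[i]) - std::log(sp[i]);
      anchors[a++] = i + 1;
    }
  }
  if (n_used > 0) value /= n_used;

  if (want_grad && n_used > 0) {
    double *gv = &g[0];
    const double sc = 1.0 / (tau * n_used);
    for (int k = 0; k < N; ++k) {
      const int off = k * n;
      for (int i = 0; i < n; ++i) {
        if (!contrib[i]) continue;
        const bool p = pv[off + i] != 0, d = dv[off + i] != 0;
        if (p || d) {
          double val = 0.0;
          const double e = ebuf[off + i];
          if (d) val += e / sd[i];
          if (p) val -= e / sp[i];
          gv[off + i] = val * sc;
        }
      }
    }
  }

  List out = List::create(_["value"] = value,
                          _["n_anchors"] = n_used,
                          _["anchors"] = anchors);
  if (want_grad) out["grad"] = g; else out["grad"] = R_NilValue;
  return out;
}
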