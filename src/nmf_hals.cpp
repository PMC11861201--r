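// HALS (column-wise coordinate descent) inner loop for Frobenius NMF.
// Restart seeding, column normalisation and ordering stay on the R side.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List nmf_hals_cpp(NumericMatrix Um, NumericMatrix W0, NumericMatrix C0,
                  int max_iter, double tol, bool update_w) {
  const int m = Um.nrow(), n = Um.ncol();
  const int s = W0.ncol();
  const double* U = REAL(Um);
  std::vector<double> W(REAL(W0), REAL(W0) + m * s);     // column-major m x s
  std::vector<double> C(REAL(C0), REAL(C0) + s * n);     // column-major s x n
  std::vector<double> UCt(m * s), CCt(s * s), WtU(s * n), WtW(s * s);
  double sumU2 = 0.0;
  for (int i = 0; i < m * n; ++i) sumU2 += U[i] * U[i];
  double loss = sumU2, loss_prev = R_PosInf;

  for (int it = 0; it < max_iter; ++it) {
    if (update_w) {
      // UCt = U * C^T ; CCt = C * C^T
      std::fill(UCt.begin(), UCt.end(), 0.0);
      std::fill(CCt.begin(), CCt.end(), 0.0);
      for (int t = 0; t < n; ++t) {
        const double* u = U + m * t;
        const double* c = &C[s * t];
        for (int k = 0; k < s; ++k) {
          const double ck = c[k];
          if (ck != 0.0) {
            double* col = &UCt[m * k];
            for (int i = 0; i < m; ++i) col[i] += u[i] * ck;
            for (int j = 0; j <= k; ++j) CCt[j + s * k] += c[j] * ck;
          }
        }
      }
      for (int k = 0; k < s; ++k)
        for (int j = 0; j < k; ++j) CCt[k + s * j] = CCt[j + s * k];
      for (int k = 0; k < s; ++k) {
        const double d = CCt[k + s * k];
        if (d <= 1e-14) continue;
        for (int i = 0; i < m; ++i) {
          double acc = 0.0;
          for (int j = 0; j < s; ++j) acc += W[i + m * j] * CCt[j + s * k];
          double w = W[i + m * k] + (UCt[i + m * k] - acc) / d;
          W[i + m * k] = w > 0.0 ? w : 0.0;
        }
      }
    }
    // WtU = W^T U ; WtW = W^T W
    for (int k = 0; k < s; ++k)
      for (int j = 0; j <= k; ++j) {
        double acc = 0.0;
        for (int i = 0; i < m; ++i) acc += W[i + m * j] * W[i + m * k];
        WtW[j + s * k] = WtW[k + s * j] = acc;
      }
    for (int t = 0; t < n; ++t) {
      const double* u = U + m * t;
      double* col = &WtU[s * t];
      for (int k = 0; k < s; ++k) {
        double acc = 0.0;
        for (int i = 0; i < m; ++i) acc += W[i + m * k] * u[i];
        col[k] = acc;
      }
    }
    for (int k = 0; k < s; ++k) {
      const double d = WtW[k + s * k];
      if (d <= 1e-14) continue;
      for (int t = 0; t < n; ++t) {
        double acc = 0.0;
        const double* c = &C[s * t];
        for (int j = 0; j < s; ++j) acc += WtW[j + s * k] * c[j];
        double v = C[k + s * t] + (WtU[k + s * t] - acc) / d;
        C[k + s * t] = v > 0.0 ? v : 0.0;
      }
    }
    // loss = ||U||^2 - 2 <WtU, C> + <WtW, C C^T>
    double cross = 0.0;
    std::fill(CCt.begin(), CCt.end(), 0.0);
    for (int t = 0; t < n; ++t) {
      const double* c = &C[s * t];
      for (int k = 0; k < s; ++k) {
        cross += WtU[k + s * t] * c[k];
        for (int j = 0; j <= k; ++j) CCt[j + s * k] += c[j] * c[k];
      }
    }
    double quad = 0.0;
    for (int k = 0; k < s; ++k)
      for (int j = 0; j < s; ++j)
        quad += WtW[j + s * k] * (j <= k ? CCt[j + s * k] : CCt[k + s * j]);
    loss = sumU2 - 2.0 * cross + quad;
    if (std::isfinite(loss_prev) &&
        std::fabs(loss_prev - loss) <= tol * std::max(loss_prev, 1e-300)) break;
    loss_prev = loss;
  }
  NumericMatrix Wout(m, s), Cout(s, n);
  std::copy(W.begin(), W.end(), REAL(Wout));
  std::copy(C.begin(), C.end(), REAL(Cout));
  return List::create(_["W"] = Wout, _["C"] = Cout,
                      _["loss"] = loss > 0.0 ? loss : 0.0);
}
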