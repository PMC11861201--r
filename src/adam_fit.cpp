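// Full-batch Adam optimisation of the keypoint displacement models with
// analytic gradients. Parameter layouts (0-based):
//   SMSM spring block (36):
//     singles, order outer_eyebrow(OF), nose(LLSAN), chin(Me):
//       [tk0, tk1, l0, l1] x 3            -> 0..11   (k = softplus(tk))
//     doubles, order inner_eyebrow(IF,CS), mouth_corner(ZM,DAO):
//       [tk0,tk1,l0,l1]m1 [tk0,tk1,l0,l1]m2 [a1,a2,lam1,lam2] -> 12..35
//   kind 0: SMSM          theta = spring block
//   kind 1: SMSM-LRM      theta = spring block + W(5x5) row-major
//   kind 2: LRM (Adam)    theta = W(5x7) row-major
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double softplus(double x) {
  return (x > 0 ? x : 0.0) + std::log1p(std::exp(-std::fabs(x)));
}
static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// keypoint/muscle rows (0-based) for the fixed anatomical wiring
static const int SING_KP[3] = {1, 2, 4};   // outer_eyebrow, nose, chin
static const int SING_MU[3] = {1, 3, 6};   // OF, LLSAN, Me
static const int DBL_KP[2] = {0, 3};       // inner_eyebrow, mouth_corner
static const int DBL_MU[2][2] = {{0, 2}, {4, 5}}; // {IF,CS}, {ZM,DAO}

// [[Rcpp::export]]
List adam_fit_cpp(NumericMatrix Um, NumericMatrix Ym, int kind,
                  NumericVector theta0, double KH, int epochs, double lr,
                  double beta1, double beta2, double pen_weight,
                  double den_min) {
  const int T = Um.ncol();
  if (Ym.ncol() != T) stop("U and Y must have the same number of samples");
  if (Um.nrow() != 7 || Ym.nrow() != 5) stop("U must be 7 x T and Y 5 x T");
  const double* U = REAL(Um);
  const double* Y = REAL(Ym);
  const int np = theta0.size();
  std::vector<double> th(theta0.begin(), theta0.end());
  std::vector<double> g(np), mom(np, 0.0), vel(np, 0.0);
  NumericVector loss_curve(epochs);

  std::vector<double> D(5 * T);          // spring displacements (kind 0/1)
  std::vector<double> invden(5 * T);     // cached 1/denominator per system
  std::vector<double> gP(5 * T);         // d loss / d prediction
  std::vector<double> gD(5 * T);
  const double denom_norm = 5.0 * static_cast<double>(T);
  const int woff = (kind == 1) ? 36 : 0;

  for (int ep = 0; ep < epochs; ++ep) {
    std::fill(g.begin(), g.end(), 0.0);
    double pen = 0.0;

    if (kind != 2) {
      for (int s = 0; s < 3; ++s) {
        const double k0 = softplus(th[4 * s]), k1 = softplus(th[4 * s + 1]);
        const double l0 = th[4 * s + 2], l1 = th[4 * s + 3];
        const int kp = SING_KP[s], mu = SING_MU[s];
        for (int t = 0; t < T; ++t) {
          const double u = U[mu + 7 * t];
          const double sv = k0 + k1 * u;
          const double inv = 1.0 / (KH + sv);
          invden[kp + 5 * t] = inv;
          D[kp + 5 * t] = sv * (l0 + l1 * u) * inv;
        }
      }
      for (int dsy = 0; dsy < 2; ++dsy) {
        const int base = 12 + 12 * dsy;
        const double k0a = softplus(th[base]), k1a = softplus(th[base + 1]);
        const double l0a = th[base + 2], l1a = th[base + 3];
        const double k0b = softplus(th[base + 4]), k1b = softplus(th[base + 5]);
        const double l0b = th[base + 6], l1b = th[base + 7];
        const double a1 = th[base + 8], a2 = th[base + 9];
        const double lm1 = th[base + 10], lm2 = th[base + 11];
        const int kp = DBL_KP[dsy];
        const int mu1 = DBL_MU[dsy][0], mu2 = DBL_MU[dsy][1];
        for (int t = 0; t < T; ++t) {
          const double u1 = U[mu1 + 7 * t], u2 = U[mu2 + 7 * t];
          const double s1 = k0a + k1a * u1, s2 = k0b + k1b * u2;
          const double den = KH + a1 * lm1 * s1 + a2 * lm2 * s2;
          const double num = a1 * s1 * (l0a + l1a * u1) + a2 * s2 * (l0b + l1b * u2);
          const double inv = 1.0 / den;
          invden[kp + 5 * t] = inv;
          D[kp + 5 * t] = num * inv;
          if (den < den_min) {
            const double v = den_min - den;
            pen += pen_weight * v * v / T;
          }
        }
      }
    }

    // predictions and loss gradient (gP); P is never materialised
    double sse = 0.0;
    if (kind == 0) {
      for (int i = 0; i < 5 * T; ++i) {
        const double e = D[i] - Y[i];
        sse += e * e;
        gP[i] = 2.0 * e / denom_norm;
      }
    } else if (kind == 1) {
      const double* W = &th[woff];
      for (int t = 0; t < T; ++t) {
        const double* d = &D[5 * t];
        for (int r = 0; r < 5; ++r) {
          const double* w = W + 5 * r;
          const double p = w[0] * d[0] + w[1] * d[1] + w[2] * d[2] +
                           w[3] * d[3] + w[4] * d[4];
          const double e = p - Y[r + 5 * t];
          sse += e * e;
          gP[r + 5 * t] = 2.0 * e / denom_norm;
        }
      }
    } else {
      const double* W = &th[0];
      for (int t = 0; t < T; ++t) {
        const double* u = U + 7 * t;
        for (int r = 0; r < 5; ++r) {
          const double* w = W + 7 * r;
          double p = 0.0;
          for (int c = 0; c < 7; ++c) p += w[c] * u[c];
          const double e = p - Y[r + 5 * t];
          sse += e * e;
          gP[r + 5 * t] = 2.0 * e / denom_norm;
        }
      }
    }
    const double loss = sse / denom_norm + pen;
    if (!std::isfinite(loss)) stop("non-finite loss at epoch %d", ep + 1);
    loss_curve[ep] = loss;

    // backward
    if (kind == 2) {
      for (int t = 0; t < T; ++t) {
        const double* u = U + 7 * t;
        for (int r = 0; r < 5; ++r) {
          const double gp = gP[r + 5 * t];
          double* gw = &g[7 * r];
          for (int c = 0; c < 7; ++c) gw[c] += gp * u[c];
        }
      }
    } else {
      if (kind == 1) {
        const double* W = &th[woff];
        for (int t = 0; t < T; ++t) {
          const double* d = &D[5 * t];
          const double* gp = &gP[5 * t];
          double* gd = &gD[5 * t];
          for (int c = 0; c < 5; ++c)
            gd[c] = W[5 * 0 + c] * gp[0] + W[5 * 1 + c] * gp[1] +
                    W[5 * 2 + c] * gp[2] + W[5 * 3 + c] * gp[3] +
                    W[5 * 4 + c] * gp[4];
          for (int r = 0; r < 5; ++r) {
            const double gpr = gp[r];
            double* gw = &g[woff + 5 * r];
            for (int c = 0; c < 5; ++c) gw[c] += gpr * d[c];
          }
        }
      } else {
        std::copy(gP.begin(), gP.end(), gD.begin());
      }
      for (int s = 0; s < 3; ++s) {
        const double tk0 = th[4 * s], tk1 = th[4 * s + 1];
        const double k0 = softplus(tk0), k1 = softplus(tk1);
        const double l0 = th[4 * s + 2], l1 = th[4 * s + 3];
        const int kp = SING_KP[s], mu = SING_MU[s];
        double g0 = 0, g1 = 0, g2 = 0, g3 = 0;
        for (int t = 0; t < T; ++t) {
          const double gd = gD[kp + 5 * t];
          const double u = U[mu + 7 * t];
          const double sv = k0 + k1 * u, L = l0 + l1 * u;
          const double inv = invden[kp + 5 * t];
          const double dk = L * KH * inv * inv;   // d dl / d k0
          const double dl = sv * inv;             // d dl / d l0
          g0 += gd * dk;
          g1 += gd * dk * u;
          g2 += gd * dl;
          g3 += gd * dl * u;
        }
        g[4 * s] += g0 * sigmoid(tk0);
        g[4 * s + 1] += g1 * sigmoid(tk1);
        g[4 * s + 2] += g2;
        g[4 * s + 3] += g3;
      }
      for (int dsy = 0; dsy < 2; ++dsy) {
        const int base = 12 + 12 * dsy;
        const double tk0a = th[base], tk1a = th[base + 1];
        const double k0a = softplus(tk0a), k1a = softplus(tk1a);
        const double l0a = th[base + 2], l1a = th[base + 3];
        const double tk0b = th[base + 4], tk1b = th[base + 5];
        const double k0b = softplus(tk0b), k1b = softplus(tk1b);
        const double l0b = th[base + 6], l1b = th[base + 7];
        const double a1 = th[base + 8], a2 = th[base + 9];
        const double lm1 = th[base + 10], lm2 = th[base + 11];
        const int kp = DBL_KP[dsy];
        const int mu1 = DBL_MU[dsy][0], mu2 = DBL_MU[dsy][1];
        double gb[12] = {0};
        for (int t = 0; t < T; ++t) {
          const double gd = gD[kp + 5 * t];
          const double u1 = U[mu1 + 7 * t], u2 = U[mu2 + 7 * t];
          const double s1 = k0a + k1a * u1, s2 = k0b + k1b * u2;
          const double L1 = l0a + l1a * u1, L2 = l0b + l1b * u2;
          const double n1 = s1 * L1, n2 = s2 * L2;
          const double inv = invden[kp + 5 * t];
          const double N = a1 * n1 + a2 * n2;
          const double Ninv2 = N * inv * inv;
          // denominator hinge-penalty gradient shares the same chain
          double gden = 0.0;
          const double den = 1.0 / inv;
          if (den < den_min) gden = -2.0 * pen_weight * (den_min - den) / T;
          const double dk0a = gd * (a1 * L1 * inv - Ninv2 * a1 * lm1) +
                              gden * a1 * lm1;
          const double dk0b = gd * (a2 * L2 * inv - Ninv2 * a2 * lm2) +
                              gden * a2 * lm2;
          gb[0] += dk0a;
          gb[1] += dk0a * u1;
          gb[2] += gd * a1 * s1 * inv;
          gb[3] += gd * a1 * s1 * inv * u1;
          gb[4] += dk0b;
          gb[5] += dk0b * u2;
          gb[6] += gd * a2 * s2 * inv;
          gb[7] += gd * a2 * s2 * inv * u2;
          gb[8] += gd * n1 * inv - Ninv2 * gd * lm1 * s1 * inv * den + gden * lm1 * s1;
          gb[9] += gd * n2 * inv - Ninv2 * gd * lm2 * s2 * inv * den + gden * lm2 * s2;
          gb[10] += -Ninv2 * gd * a1 * s1 + gden * a1 * s1;
          gb[11] += -Ninv2 * gd * a2 * s2 + gden * a2 * s2;
        }
        g[base] += gb[0] * sigmoid(tk0a);
        g[base + 1] += gb[1] * sigmoid(tk1a);
        g[base + 2] += gb[2];
        g[base + 3] += gb[3];
        g[base + 4] += gb[4] * sigmoid(tk0b);
        g[base + 5] += gb[5] * sigmoid(tk1b);
        g[base + 6] += gb[6];
        g[base + 7] += gb[7];
        for (int j = 8; j < 12; ++j) g[base + j] += gb[j];
      }
    }

    // Adam update
    const double bc1 = 1.0 - std::pow(beta1, ep + 1);
    const double bc2 = 1.0 - std::pow(beta2, ep + 1);
    for (int j = 0; j < np; ++j) {
      mom[j] = beta1 * mom[j] + (1.0 - beta1) * g[j];
      vel[j] = beta2 * vel[j] + (1.0 - beta2) * g[j] * g[j];
      th[j] -= lr * (mom[j] / bc1) / (std::sqrt(vel[j] / bc2) + 1e-8);
    }
  }

  return List::create(_["theta"] = NumericVector(th.begin(), th.end()),
                      _["loss_curve"] = loss_curve);
}
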