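#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Kalman filter pass for a zero-mean ARMA(p,q) process in Harvey's
// state-space form, with the innovation variance concentrated out
// (the filter is run at sigma^2 = 1).
//
//   state dim r = max(p, q + 1)
//   T: first column = (phi_1..phi_r), superdiagonal identity shift
//   R = (1, theta_1, .., theta_q, 0, ..)',  Z = e_1'
//
// The filter is initialised at the exact stationary state covariance
// (Lyapunov equation, solved below). Returns sum(log F_t),
// sum(v_t^2 / F_t) and, for forecasting, the one-step-ahead predicted
// state a_{n+1|n} and its covariance; ok = false flags a non-stationary
// parameter point or a degenerate prediction variance.
// Stationary state covariance: solve vec(P) = (I - T (x) T)^{-1} vec(R R')
// by Gaussian elimination with partial pivoting (r <= a handful, so the
// r^2 x r^2 system is tiny). Returns false on a singular system
// (non-stationary parameters).
static bool stationary_cov(const std::vector<double>& Tm,
                           const std::vector<double>& Rv,
                           int r, std::vector<double>& P) {
  const int m = r * r;
  std::vector<double> A(m * m, 0.0), b(m);
  // A = I - kron(T, T); kron index: row (i1*r+i2), col (j1*r+j2) -> T(i1,j1)*T(i2,j2)
  for (int i1 = 0; i1 < r; ++i1)
    for (int i2 = 0; i2 < r; ++i2)
      for (int j1 = 0; j1 < r; ++j1)
        for (int j2 = 0; j2 < r; ++j2) {
          const int row = i1 * r + i2, col = j1 * r + j2;
          A[row * m + col] = (row == col ? 1.0 : 0.0)
                           - Tm[i1 + j1 * r] * Tm[i2 + j2 * r];
        }
  for (int i1 = 0; i1 < r; ++i1)
    for (int i2 = 0; i2 < r; ++i2)
      b[i1 * r + i2] = Rv[i1] * Rv[i2];
  // in-place LU with partial pivoting
  std::vector<int> piv(m);
  for (int k = 0; k < m; ++k) {
    int imax = k;
    double amax = std::fabs(A[k * m + k]);
    for (int i = k + 1; i < m; ++i) {
      const double v = std::fabs(A[i * m + k]);
      if (v > amax) { amax = v; imax = i; }
    }
    if (amax < 1e-12) return false;
    if (imax != k) {
      for (int j = 0; j < m; ++j) std::swap(A[k * m + j], A[imax * m + j]);
      std::swap(b[k], b[imax]);
    }
    for (int i = k + 1; i < m; ++i) {
      const double f = A[i * m + k] / A[k * m + k];
      if (f == 0.0) continue;
      for (int j = k; j < m; ++j) A[i * m + j] -= f * A[k * m + j];
      b[i] -= f * b[k];
    }
  }
  P.assign(m, 0.0);
  for (int i = m - 1; i >= 0; --i) {
    double s = b[i];
    for (int j = i + 1; j < m; ++j) s -= A[i * m + j] * P[j];
    P[i] = s / A[i * m + i];
  }
  for (int i = 0; i < m; ++i)
    if (!std::isfinite(P[i])) return false;
  return true;
}

// [[Rcpp::export]]
List arma_kalman(NumericVector y, NumericVector phi, NumericVector theta) {
  const int n = y.size();
  const int p = phi.size(), q = theta.size();
  const int r = std::max(p, q + 1);
  std::vector<double> phif(r, 0.0), Rv(r, 0.0);
  for (int i = 0; i < p; ++i) phif[i] = phi[i];
  Rv[0] = 1.0;
  for (int i = 0; i < q; ++i) Rv[i + 1] = theta[i];

  std::vector<double> Tm(r * r, 0.0);
  for (int i = 0; i < p; ++i) Tm[i + 0 * r] = phi[i];
  for (int i = 0; i + 1 < r; ++i) Tm[i + (i + 1) * r] = 1.0;
  std::vector<double> P;
  if (!stationary_cov(Tm, Rv, r, P)) {
    return List::create(_["ok"] = false, _["sumlog"] = 0.0, _["ssq"] = 0.0,
                        _["n"] = n, _["a_pred"] = NumericVector(r),
                        _["P_pred"] = NumericVector(r * r));
  }
  std::vector<double> a(r, 0.0);
  std::vector<double> af(r), anew(r), Pf(r * r), B(r * r), Pnew(r * r);
  double sumlog = 0.0, ssq = 0.0;
  bool ok = true;

  for (int t = 0; t < n; ++t) {
    const double v = y[t] - a[0];
    const double F = P[0];
    if (!(F > 0.0) || !std::isfinite(F)) { ok = false; break; }
    ssq += v * v / F;
    sumlog += std::log(F);
    // filtered state/covariance (Z = e1, so the gain column is P[,0])
    for (int i = 0; i < r; ++i) af[i] = a[i] + P[i] * (v / F);
    for (int j = 0; j < r; ++j)
      for (int i = 0; i < r; ++i)
        Pf[i + j * r] = P[i + j * r] - P[i] * P[j] / F;
    // predict: a = T af,  P = T Pf T' + R R'
    for (int i = 0; i < r; ++i)
      anew[i] = phif[i] * af[0] + (i + 1 < r ? af[i + 1] : 0.0);
    for (int j = 0; j < r; ++j)
      for (int i = 0; i < r; ++i)
        B[i + j * r] = phif[i] * Pf[0 + j * r] + (i + 1 < r ? Pf[(i + 1) + j * r] : 0.0);
    for (int j = 0; j < r; ++j)
      for (int i = 0; i < r; ++i)
        Pnew[i + j * r] = phif[j] * B[i + 0 * r]
                        + (j + 1 < r ? B[i + (j + 1) * r] : 0.0)
                        + Rv[i] * Rv[j];
    a = anew;
    P = Pnew;
  }

  return List::create(_["ok"] = ok, _["sumlog"] = sumlog, _["ssq"] = ssq,
                      _["n"] = n, _["a_pred"] = NumericVector(a.begin(), a.end()),
                      _["P_pred"] = NumericVector(P.begin(), P.end()));
}
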