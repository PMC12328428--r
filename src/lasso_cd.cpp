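#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Weighted L1-penalized logistic regression path by IRLS + cyclic coordinate
// descent with soft thresholding and an active-set strategy. X is expected
// standardized; w are observation weights normalized to sum 1; pen are
// per-coefficient penalty factors (>= cap forces the coefficient to zero);
// the intercept is unpenalized. Returns a (p+1) x nlambda coefficient matrix
// (intercept in row 0), with warm starts along the lambda grid.

// [[Rcpp::export]]
NumericMatrix lasso_logistic_path_cpp(NumericMatrix X, NumericVector y,
                                      NumericVector w, NumericVector pen,
                                      NumericVector lambdas, double pen_cap,
                                      double tol, int max_outer,
                                      int max_inner) {
  const int n = X.nrow(), p = X.ncol(), nl = lambdas.size();
  NumericMatrix out(p + 1, nl);
  std::vector<double> beta(p, 0.0);
  double b0 = 0.0;
  std::vector<double> eta(n, 0.0), v(n), r(n);
  std::vector<int> active;
  std::vector<char> in_active(p, 0);

  // initialize intercept at weighted logit of prevalence
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += w[i] * y[i];
  if (ybar < 1e-10) ybar = 1e-10;
  if (ybar > 1 - 1e-10) ybar = 1 - 1e-10;
  b0 = std::log(ybar / (1.0 - ybar));

  // single-coordinate update on the quadratic approximation; returns |delta|
  auto update_coord = [&](int j, double lam) -> double {
    double num = 0.0, den = 0.0;
    for (int i = 0; i < n; ++i) {
      num += X(i, j) * r[i];
      den += v[i] * X(i, j) * X(i, j);
    }
    if (den <= 0) return 0.0;
    const double zj = num + den * beta[j];
    const double thr = lam * pen[j];
    double bnew;
    if (zj > thr) bnew = (zj - thr) / den;
    else if (zj < -thr) bnew = (zj + thr) / den;
    else bnew = 0.0;
    const double d = bnew - beta[j];
    if (d != 0.0) {
      for (int i = 0; i < n; ++i) r[i] -= v[i] * X(i, j) * d;
      beta[j] = bnew;
      if (!in_active[j]) { in_active[j] = 1; active.push_back(j); }
    }
    return std::fabs(d);
  };

  auto update_intercept = [&]() -> double {
    double num = 0.0, den = 0.0;
    for (int i = 0; i < n; ++i) { num += r[i]; den += v[i]; }
    const double d = num / den;
    if (d != 0.0) {
      b0 += d;
      for (int i = 0; i < n; ++i) r[i] -= v[i] * d;
    }
    return std::fabs(d);
  };

  for (int l = 0; l < nl; ++l) {
    const double lam = lambdas[l];
    for (int outer = 0; outer < max_outer; ++outer) {
      // quadratic approximation at current (b0, beta)
      for (int i = 0; i < n; ++i) eta[i] = b0;
      for (int j = 0; j < p; ++j) {
        if (beta[j] != 0.0) {
          const double bj = beta[j];
          for (int i = 0; i < n; ++i) eta[i] += X(i, j) * bj;
        }
      }
      for (int i = 0; i < n; ++i) {
        double m = 1.0 / (1.0 + std::exp(-eta[i]));
        if (m < 1e-6) m = 1e-6;
        if (m > 1 - 1e-6) m = 1 - 1e-6;
        const double vv = m * (1.0 - m);
        v[i] = w[i] * vv;
        r[i] = w[i] * (y[i] - m);  // v * working residual
      }
      // one full sweep (may grow the active set), then active-set sweeps
      double full_delta = update_intercept();
      for (int j = 0; j < p; ++j) {
        if (pen[j] >= pen_cap) continue;
        const double d = update_coord(j, lam);
        if (d > full_delta) full_delta = d;
      }
      for (int inner = 0; inner < max_inner; ++inner) {
        double max_delta = update_intercept();
        for (size_t a = 0; a < active.size(); ++a) {
          const double d = update_coord(active[a], lam);
          if (d > max_delta) max_delta = d;
        }
        if (max_delta < tol) break;
      }
      if (full_delta < tol) break;  // IRLS converged
    }
    out(0, l) = b0;
    for (int j = 0; j < p; ++j) out(j + 1, l) = beta[j];
  }
  return out;
}
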