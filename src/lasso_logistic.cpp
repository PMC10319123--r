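#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// L1-penalized logistic regression path by IRLS + cyclic coordinate
// descent (unpenalized intercept). Minimizes
//   -(1/n) * sum_i [ y_i * eta_i - log(1 + exp(eta_i)) ] + lambda * ||beta||_1
// over a decreasing lambda path with warm starts. Small dense problems
// only (the congruency feature matrices are S x K with K ~ 10); the
// permutation test refits this model tens of thousands of times, which
// is why the inner loop is compiled.
//
// [[Rcpp::export(name = ".lasso_logistic_path_cpp")]]
NumericMatrix lasso_logistic_path_cpp(NumericMatrix X, NumericVector y,
                                      NumericVector lambda,
                                      double tol = 1e-6, int max_irls = 8,
                                      int max_cd = 50) {
  const int n = X.nrow(), p = X.ncol(), L = lambda.size();
  NumericMatrix coef(p + 1, L); // row 0: intercept
  std::vector<double> beta(p, 0.0);
  double b0 = 0.0;

  std::vector<double> eta(n), prob(n), w(n), z(n), r(n), xwx(p);

  // null deviance (intercept-only), for saturation-based path stopping
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  double nulldev = 0.0;
  if (ybar > 0.0 && ybar < 1.0)
    for (int i = 0; i < n; ++i)
      nulldev += -2.0 * (y[i] * std::log(ybar) +
                         (1.0 - y[i]) * std::log(1.0 - ybar));

  for (int l = 0; l < L; ++l) {
    const double lam = lambda[l];
    for (int it = 0; it < max_irls; ++it) {
      // quadratic approximation at the current linear predictor
      double dev = 0.0;
      for (int i = 0; i < n; ++i) {
        double e = b0;
        for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
        eta[i] = e;
        double pr = 1.0 / (1.0 + std::exp(-e));
        if (pr < 1e-5) pr = 1e-5;
        if (pr > 1.0 - 1e-5) pr = 1.0 - 1e-5;
        prob[i] = pr;
        w[i] = pr * (1.0 - pr);
        z[i] = e + (y[i] - pr) / w[i];
        r[i] = z[i] - e; // working residual at current coefficients
        dev += -2.0 * (y[i] * std::log(pr) + (1.0 - y[i]) * std::log(1.0 - pr));
      }
      // fit is saturated; further refinement is numerically meaningless
      if (nulldev > 0.0 && 1.0 - dev / nulldev > 0.999) break;
      for (int j = 0; j < p; ++j) {
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += w[i] * X(i, j) * X(i, j);
        xwx[j] = s / n;
      }
      // solve the weighted lasso subproblem by coordinate descent with
      // an active-set strategy: full sweeps establish the active set,
      // then only active coordinates are iterated to convergence
      std::vector<bool> active(p, true);
      bool full_sweep = true;
      for (int cd = 0; cd < max_cd; ++cd) {
        double maxd = 0.0;
        // intercept (unpenalized)
        double sw = 0.0, swr = 0.0;
        for (int i = 0; i < n; ++i) { sw += w[i]; swr += w[i] * r[i]; }
        double d0 = swr / sw;
        if (std::fabs(d0) > maxd) maxd = std::fabs(d0);
        b0 += d0;
        for (int i = 0; i < n; ++i) r[i] -= d0;
        for (int j = 0; j < p; ++j) {
          if (!full_sweep && !active[j]) continue;
          double g = 0.0;
          for (int i = 0; i < n; ++i) g += w[i] * X(i, j) * r[i];
          g = g / n + xwx[j] * beta[j];
          double bnew;
          if (g > lam) bnew = (g - lam) / xwx[j];
          else if (g < -lam) bnew = (g + lam) / xwx[j];
          else bnew = 0.0;
          double d = bnew - beta[j];
          if (d != 0.0) {
            beta[j] = bnew;
            for (int i = 0; i < n; ++i) r[i] -= X(i, j) * d;
            if (std::fabs(d) > maxd) maxd = std::fabs(d);
          }
          if (full_sweep) active[j] = (bnew != 0.0);
        }
        if (maxd < tol) {
          if (full_sweep) break;
          full_sweep = true;  // verify on a final full sweep
        } else {
          full_sweep = false;
        }
      }
      // convergence of the outer IRLS loop: change in linear predictor
      double delta_eta = 0.0;
      for (int i = 0; i < n; ++i) {
        double e = b0;
        for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
        double d = e - eta[i];
        if (std::fabs(d) > delta_eta) delta_eta = std::fabs(d);
      }
      if (delta_eta < 1e-5 * (1.0 + std::fabs(b0))) break;
    }
    coef(0, l) = b0;
    for (int j = 0; j < p; ++j) coef(j + 1, l) = beta[j];
    // stop descending the path once the fit saturates (deviance ratio
    // > 0.999, as glmnet does); carry coefficients forward
    if (nulldev > 0.0) {
      double dev = 0.0;
      for (int i = 0; i < n; ++i) {
        double pr = prob[i];
        dev += -2.0 * (y[i] * std::log(pr) + (1.0 - y[i]) * std::log(1.0 - pr));
      }
      if (1.0 - dev / nulldev > 0.999) {
        for (int l2 = l + 1; l2 < L; ++l2)
          for (int j = 0; j <= p; ++j) coef(j, l2) = coef(j, l);
        break;
      }
    }
  }
  return coef;
}
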