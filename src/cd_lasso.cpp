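#include <Rcpp.h>
using namespace Rcpp;

// Coordinate descent for the lasso with unpenalized intercept, on the
// glmnet-scale objective  (1/(2m)) * sum_k (y_k - b0 - x_k'beta)^2 +
// lambda * ||beta||_1, where the sums run over the m included
// observations. Centering is handled implicitly: the residual vector holds
// centered residuals and the intercept is recovered at the end as
// b0 = mean(y) - mean(x)'beta. One observation can be excluded (leave-one-
// out) without copying the design matrix; its residual entry is kept
// consistent but skipped in all inner products.

static inline double soft(double u, double lambda) {
  if (u > lambda) return u - lambda;
  if (u < -lambda) return u + lambda;
  return 0.0;
}

// Update coordinate j given centered residuals r (length n, excluded row
// consistent but skipped). Returns the squared scaled step v_j * d^2.
static inline double cd_update(const double* xj, double* r, double* beta,
                               int j, int n, int m, int exclude,
                               double meanj, double vj, double lambda) {
  double dot = 0.0;
  for (int k = 0; k < n; ++k) dot += xj[k] * r[k];
  if (exclude >= 0) dot -= xj[exclude] * r[exclude];
  double g = dot / m;
  double bnew = soft(g + vj * beta[j], lambda) / vj;
  double d = bnew - beta[j];
  if (d == 0.0) return 0.0;
  for (int k = 0; k < n; ++k) r[k] -= d * (xj[k] - meanj);
  beta[j] = bnew;
  return vj * d * d;
}

// One full solve. X: n x p column-major, exclude: 0-based row to leave out
// (or -1). beta is modified in place (warm start in, solution out).
// Returns the intercept.
static double cd_solve(const double* X, const double* y, int n, int p,
                       double lambda, std::vector<double>& beta,
                       int exclude, int maxit, double tol,
                       const double* Sx, const double* Sxx, double Sy,
                       std::vector<double>& mean, std::vector<double>& v,
                       std::vector<double>& r, std::vector<int>& active) {
  const int m = (exclude >= 0) ? n - 1 : n;
  for (int j = 0; j < p; ++j) {
    double sx = Sx[j], sxx = Sxx[j];
    if (exclude >= 0) {
      double xi = X[(size_t)j * n + exclude];
      sx -= xi;
      sxx -= xi * xi;
    }
    double mj = sx / m;
    mean[j] = mj;
    v[j] = sxx / m - mj * mj;
    if (v[j] < 0) v[j] = 0;
  }
  double my = Sy;
  if (exclude >= 0) my -= y[exclude];
  my /= m;

  // centered residuals r_k = (y_k - my) - sum_j (x_kj - mean_j) beta_j,
  // maintained for all n rows (the excluded row is skipped in sums only)
  for (int k = 0; k < n; ++k) r[k] = y[k] - my;
  for (int j = 0; j < p; ++j) {
    double bj = beta[j];
    if (bj == 0.0) continue;
    const double* xj = X + (size_t)j * n;
    const double mj = mean[j];
    for (int k = 0; k < n; ++k) r[k] -= bj * (xj[k] - mj);
  }

  for (int it = 0; it < maxit; ++it) {
    // full sweep
    double maxd = 0.0;
    for (int j = 0; j < p; ++j) {
      if (v[j] <= 0) { beta[j] = 0.0; continue; }
      double crit = cd_update(X + (size_t)j * n, r.data(), beta.data(), j,
                              n, m, exclude, mean[j], v[j], lambda);
      if (crit > maxd) maxd = crit;
    }
    if (maxd < tol) break;

    // iterate on the active set until stable, then re-check with a full sweep
    active.clear();
    for (int j = 0; j < p; ++j) if (beta[j] != 0.0) active.push_back(j);
    for (int inner = 0; inner < maxit; ++inner) {
      double maxda = 0.0;
      for (size_t a = 0; a < active.size(); ++a) {
        int j = active[a];
        double crit = cd_update(X + (size_t)j * n, r.data(), beta.data(), j,
                                n, m, exclude, mean[j], v[j], lambda);
        if (crit > maxda) maxda = crit;
      }
      if (maxda < tol) break;
    }
  }

  double b0 = my;
  for (int j = 0; j < p; ++j) b0 -= mean[j] * beta[j];
  return b0;
}

static void col_moments(const double* X, const double* y, int n, int p,
                        std::vector<double>& Sx, std::vector<double>& Sxx,
                        double& Sy) {
  for (int j = 0; j < p; ++j) {
    const double* xj = X + (size_t)j * n;
    double sx = 0.0, sxx = 0.0;
    for (int k = 0; k < n; ++k) { sx += xj[k]; sxx += xj[k] * xj[k]; }
    Sx[j] = sx; Sxx[j] = sxx;
  }
  Sy = 0.0;
  for (int k = 0; k < n; ++k) Sy += y[k];
}

// [[Rcpp::export(name = ".cd_lasso_fit")]]
List cd_lasso_fit(NumericMatrix X, NumericVector y, double lambda,
                  NumericVector beta_init, int exclude = -1,
                  int maxit = 1000, double tol = 1e-11) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("length(y) != nrow(X)");
  if (beta_init.size() != p) stop("length(beta_init) != ncol(X)");
  std::vector<double> Sx(p), Sxx(p);
  double Sy;
  col_moments(X.begin(), y.begin(), n, p, Sx, Sxx, Sy);

  std::vector<double> beta(beta_init.begin(), beta_init.end());
  std::vector<double> mean(p), v(p), r(n);
  std::vector<int> active;
  double b0 = cd_solve(X.begin(), y.begin(), n, p, lambda, beta, exclude,
                       maxit, tol, Sx.data(), Sxx.data(), Sy, mean, v, r,
                       active);
  return List::create(_["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["intercept"] = b0);
}

// Leave-one-out signature scores at a fixed lambda: for each row i, refit
// the lasso on the remaining rows (warm-started at the full-data solution)
// and score row i as the intercept-free weighted sum x_i'beta^{(-i)}.
// [[Rcpp::export(name = ".cd_lasso_loo_scores")]]
NumericVector cd_lasso_loo_scores(NumericMatrix X, NumericVector y,
                                  double lambda, NumericVector beta_full,
                                  int maxit = 1000, double tol = 1e-11) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("length(y) != nrow(X)");
  if (beta_full.size() != p) stop("length(beta_full) != ncol(X)");
  std::vector<double> Sx(p), Sxx(p);
  double Sy;
  col_moments(X.begin(), y.begin(), n, p, Sx, Sxx, Sy);

  NumericVector scores(n);
  std::vector<double> beta(p);
  std::vector<double> mean(p), v(p), r(n);
  std::vector<int> active;
  for (int i = 0; i < n; ++i) {
    std::copy(beta_full.begin(), beta_full.end(), beta.begin());
    cd_solve(X.begin(), y.begin(), n, p, lambda, beta, i, maxit, tol,
             Sx.data(), Sxx.data(), Sy, mean, v, r, active);
    double s = 0.0;
    const double* xr = X.begin();
    for (int j = 0; j < p; ++j) {
      if (beta[j] != 0.0) s += xr[(size_t)j * n + i] * beta[j];
    }
    scores[i] = s;
    if ((i & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return scores;
}
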