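#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Cyclic coordinate descent for the elastic net objective
//   (1/2n) * sum_i (y_i - b0 - x_i.beta)^2
//        + lambda * ( alpha*||beta||_1 + (1-alpha)/2*||beta||_2^2 )
// Warm-started along a decreasing lambda path with an ever-active set:
// sweeps over the active set until convergence, then one full sweep to
// admit violators; repeat until the full sweep moves nothing.

static inline double soft_thresh(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

struct EnetWork {
  int n, p;
  const double *X;              // n x p, column-major
  std::vector<double> r;        // residual y - b0 - X beta
  std::vector<double> beta;
  std::vector<double> xx;       // (1/n) sum_i x_ij^2
  std::vector<int> active;      // ever-active indices
  std::vector<char> is_active;
  double b0;
  bool intercept;

  EnetWork(const double *X_, int n_, int p_, const double *y,
           bool intercept_)
      : n(n_), p(p_), X(X_), r(y, y + n_), beta(p_, 0.0), xx(p_),
        is_active(p_, 0), b0(0.0), intercept(intercept_) {
    for (int j = 0; j < p; ++j) {
      const double *xj = X + (size_t)j * n;
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
      xx[j] = s / n;
    }
    if (intercept) recenter();
  }

  void recenter() {
    double m = 0.0;
    for (int i = 0; i < n; ++i) m += r[i];
    m /= n;
    if (m != 0.0) {
      b0 += m;
      for (int i = 0; i < n; ++i) r[i] -= m;
    }
  }

  // One coordinate update; returns |delta beta_j|
  inline double update(int j, double l1, double l2) {
    if (xx[j] <= 1e-12) return 0.0;   // constant column: excluded
    const double *xj = X + (size_t)j * n;
    double dot = 0.0;
    for (int i = 0; i < n; ++i) dot += xj[i] * r[i];
    double z = dot / n + xx[j] * beta[j];
    double bnew = soft_thresh(z, l1) / (xx[j] + l2);
    double d = bnew - beta[j];
    if (d != 0.0) {
      for (int i = 0; i < n; ++i) r[i] -= d * xj[i];
      beta[j] = bnew;
      if (!is_active[j] && bnew != 0.0) {
        is_active[j] = 1;
        active.push_back(j);
      }
    }
    return std::fabs(d);
  }

  // Solve at one (l1, l2); returns false if max_iter hit
  bool solve(double l1, double l2, double tol, int max_iter) {
    int iter = 0;
    for (;;) {
      // iterate on the ever-active set
      for (;;) {
        double maxd = 0.0;
        for (size_t k = 0; k < active.size(); ++k) {
          double d = update(active[k], l1, l2);
          if (d > maxd) maxd = d;
        }
        if (intercept) recenter();
        if (maxd < tol) break;
        if (++iter > max_iter) return false;
      }
      // full sweep to admit violators
      double maxd = 0.0;
      for (int j = 0; j < p; ++j) {
        double d = update(j, l1, l2);
        if (d > maxd) maxd = d;
      }
      if (intercept) recenter();
      if (maxd < tol) return true;
      if (++iter > max_iter) return false;
    }
  }
};

// Fit the full path on X as given (no internal standardization).
// lambda must be sorted in decreasing order by the caller.
// [[Rcpp::export]]
List enet_path_dense(NumericMatrix X, NumericVector y, double alpha,
                     NumericVector lambda, double tol, int max_iter,
                     bool intercept) {
  int n = X.nrow(), p = X.ncol(), L = lambda.size();
  if ((int)y.size() != n) stop("length(y) must equal nrow(X)");
  for (int i = 0; i < n * p; ++i)
    if (!R_finite(X[i])) stop("non-finite value in X");
  for (int i = 0; i < n; ++i)
    if (!R_finite(y[i])) stop("non-finite value in y");
  EnetWork w(REAL(X), n, p, REAL(y), intercept);
  NumericMatrix B(p, L);
  NumericVector b0(L);
  LogicalVector converged(L);
  for (int l = 0; l < L; ++l) {
    double lam = lambda[l];
    converged[l] = w.solve(lam * alpha, lam * (1.0 - alpha), tol, max_iter);
    for (int j = 0; j < p; ++j) B(j, l) = w.beta[j];
    b0[l] = w.b0;
  }
  return List::create(_["beta"] = B, _["b0"] = b0,
                      _["converged"] = converged);
}

// One CV fold: standardize the training block (population sd), transform
// the held-out block with training parameters, fit the warm-started path,
// and return held-out RMSE per lambda in training-response units.
// [[Rcpp::export]]
NumericVector enet_cv_fold(NumericMatrix Xtr, NumericVector ytr,
                           NumericMatrix Xte, NumericVector yte,
                           double alpha, NumericVector lambda, double tol,
                           int max_iter, int df_max) {
  int n = Xtr.nrow(), p = Xtr.ncol(), m = Xte.nrow(), L = lambda.size();
  if (Xte.ncol() != p) stop("train/test predictor mismatch");
  std::vector<double> mu(p), sd(p);
  std::vector<double> Xs((size_t)n * p);
  const double *xtr = REAL(Xtr);
  for (int j = 0; j < p; ++j) {
    const double *c = xtr + (size_t)j * n;
    double m1 = 0.0;
    for (int i = 0; i < n; ++i) m1 += c[i];
    m1 /= n;
    double v = 0.0;
    for (int i = 0; i < n; ++i) v += (c[i] - m1) * (c[i] - m1);
    v /= n;                                  // population variance
    double s = std::sqrt(v);
    mu[j] = m1;
    sd[j] = s;
    double *o = &Xs[(size_t)j * n];
    if (s < 1e-10) {
      for (int i = 0; i < n; ++i) o[i] = 0.0; // constant: drops out
    } else {
      for (int i = 0; i < n; ++i) o[i] = (c[i] - m1) / s;
    }
  }
  double my = 0.0, vy = 0.0;
  for (int i = 0; i < n; ++i) my += ytr[i];
  my /= n;
  for (int i = 0; i < n; ++i) vy += (ytr[i] - my) * (ytr[i] - my);
  vy /= n;
  double sy = std::sqrt(vy);
  if (sy < 1e-10) stop("constant response in CV fold");
  std::vector<double> ys(n);
  for (int i = 0; i < n; ++i) ys[i] = (ytr[i] - my) / sy;

  EnetWork w(Xs.data(), n, p, ys.data(), true);
  const double *xte = REAL(Xte);
  NumericVector rmse(L);
  bool saturated = false;
  for (int l = 0; l < L; ++l) {
    if (saturated) {           // model past interpolation: extend flat
      rmse[l] = rmse[l - 1];
      continue;
    }
    double lam = lambda[l];
    w.solve(lam * alpha, lam * (1.0 - alpha), tol, max_iter);
    if (df_max > 0) {
      int nnz = 0;
      for (size_t k = 0; k < w.active.size(); ++k)
        if (w.beta[w.active[k]] != 0.0) ++nnz;
      if (nnz > df_max) saturated = true;
    }
    // predict held-out samples from the active set only
    std::vector<double> pred(m, w.b0);
    for (size_t k = 0; k < w.active.size(); ++k) {
      int j = w.active[k];
      double b = w.beta[j];
      if (b == 0.0 || sd[j] < 1e-10) continue;
      const double *c = xte + (size_t)j * m;
      double bs = b / sd[j], off = b * mu[j] / sd[j];
      for (int i = 0; i < m; ++i) pred[i] += bs * c[i] - off;
    }
    double sse = 0.0;
    for (int i = 0; i < m; ++i) {
      double e = (yte[i] - my) / sy - pred[i];
      sse += e * e;
    }
    rmse[l] = sy * std::sqrt(sse / m);       // back to response units
  }
  return rmse;
}
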