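#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Soft-margin SVM dual solved by sequential minimal optimization on a
// precomputed kernel matrix, with an incrementally maintained decision-value
// cache. Deterministic: the second index of each working pair is chosen by
// the max |E_i - E_j| heuristic with index order as the tie-break, no RNG.
//
// K: n x n kernel matrix, y in {-1, +1}, C > 0.
// Returns alpha and b such that f(x) = sum_i alpha_i y_i K(x_i, x) + b.
// [[Rcpp::export]]
List smo_train(const NumericMatrix K, const NumericVector y, double C,
               double tol = 1e-3, int max_passes = 5, int max_sweeps = 400) {
  const int n = K.nrow();
  NumericVector alpha(n, 0.0);
  double b = 0.0;
  std::vector<double> f(n, 0.0); // f_k = sum alpha_i y_i K(i,k) + b

  int passes = 0, sweeps = 0;
  while (passes < max_passes && sweeps < max_sweeps) {
    int num_changed = 0;
    ++sweeps;
    for (int i = 0; i < n; ++i) {
      double Ei = f[i] - y[i];
      bool viol = (y[i] * Ei < -tol && alpha[i] < C) ||
                  (y[i] * Ei > tol && alpha[i] > 0.0);
      if (!viol) continue;

      int j = -1;
      double best = -1.0;
      for (int k = 0; k < n; ++k) {
        if (k == i) continue;
        double d = std::fabs(Ei - (f[k] - y[k]));
        if (d > best) { best = d; j = k; }
      }
      if (j < 0) continue;
      double Ej = f[j] - y[j];

      double ai_old = alpha[i], aj_old = alpha[j];
      double L, H;
      if (y[i] != y[j]) {
        L = std::max(0.0, aj_old - ai_old);
        H = std::min(C, C + aj_old - ai_old);
      } else {
        L = std::max(0.0, ai_old + aj_old - C);
        H = std::min(C, ai_old + aj_old);
      }
      if (L >= H) continue;
      double eta = 2.0 * K(i, j) - K(i, i) - K(j, j);
      if (eta >= 0.0) continue;

      double aj = aj_old - y[j] * (Ei - Ej) / eta;
      aj = std::min(H, std::max(L, aj));
      if (std::fabs(aj - aj_old) < 1e-7) continue;
      double ai = ai_old + y[i] * y[j] * (aj_old - aj);

      double b1 = b - Ei - y[i] * (ai - ai_old) * K(i, i) -
                  y[j] * (aj - aj_old) * K(i, j);
      double b2 = b - Ej - y[i] * (ai - ai_old) * K(i, j) -
                  y[j] * (aj - aj_old) * K(j, j);
      double b_new;
      if (ai > 0.0 && ai < C) b_new = b1;
      else if (aj > 0.0 && aj < C) b_new = b2;
      else b_new = 0.5 * (b1 + b2);

      double di = y[i] * (ai - ai_old), dj = y[j] * (aj - aj_old);
      for (int k = 0; k < n; ++k)
        f[k] += di * K(i, k) + dj * K(j, k) + (b_new - b);

      alpha[i] = ai;
      alpha[j] = aj;
      b = b_new;
      ++num_changed;
    }
    if (num_changed == 0) ++passes; else passes = 0;
  }
  return List::create(_["alpha"] = alpha, _["b"] = b, _["sweeps"] = sweeps);
}

// Gaussian RBF kernel matrix between rows of X and rows of Y.
// denom = 2*sigma^2 (default kernel) or sigma^2 ("plain" variant).
// [[Rcpp::export]]
NumericMatrix rbf_kernel_matrix(const NumericMatrix X, const NumericMatrix Y,
                                double denom) {
  const int n = X.nrow(), m = Y.nrow(), d = X.ncol();
  NumericMatrix K(n, m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = X(i, k) - Y(j, k);
        s += diff * diff;
      }
      K(i, j) = std::exp(-s / denom);
    }
  }
  return K;
}
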