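#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Kraskov-Stoegbauer-Grassberger (KSG, algorithm 1) mutual information
// estimator between two multivariate series, using Chebyshev (max) norms.
// I = psi(k) + psi(N) - < psi(nx_i + 1) + psi(ny_i + 1) >
// where nx_i counts neighbours of i strictly inside the joint kth-NN
// distance eps_i, in the X marginal (resp. Y).
//
// O(N^2) pairwise scan; N ~ 1e4 and d ~ 3 keep this well under a second.

static inline double cheb(const double* a, const double* b, int d) {
  double m = 0.0;
  for (int c = 0; c < d; ++c) {
    double v = std::abs(a[c] - b[c]);
    if (v > m) m = v;
  }
  return m;
}

// [[Rcpp::export]]
double ksg_mi_cpp(NumericMatrix X, NumericMatrix Y, int k) {
  const int n = X.nrow();
  const int dx = X.ncol(), dy = Y.ncol();
  if (Y.nrow() != n) stop("series length mismatch");
  if (k < 1 || k >= n) stop("k must be in [1, n-1]");

  // row-major copies for cache-friendly scans
  std::vector<double> x(n * dx), y(n * dy);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < dx; ++c) x[i * dx + c] = X(i, c);
    for (int c = 0; c < dy; ++c) y[i * dy + c] = Y(i, c);
  }

  std::vector<double> dxv(n), dyv(n), dz(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    const double* xi = &x[i * dx];
    const double* yi = &y[i * dy];
    for (int j = 0; j < n; ++j) {
      double a = cheb(xi, &x[j * dx], dx);
      double b = cheb(yi, &y[j * dy], dy);
      dxv[j] = a;
      dyv[j] = b;
      dz[j] = a > b ? a : b;
    }
    dz[i] = R_PosInf; // exclude self
    std::vector<double> tmp(dz);
    std::nth_element(tmp.begin(), tmp.begin() + (k - 1), tmp.end());
    const double eps = tmp[k - 1]; // joint distance to kth neighbour
    int nx = 0, ny = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (dxv[j] < eps) ++nx;
      if (dyv[j] < eps) ++ny;
    }
    acc += R::digamma(nx + 1.0) + R::digamma(ny + 1.0);
  }
  double I = R::digamma((double)k) + R::digamma((double)n) - acc / n;
  return I;
}
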