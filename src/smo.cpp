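#include <Rcpp.h>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Sequential minimal optimization for the soft-margin kernel SVM dual:
//   min_a 1/2 sum_ij a_i a_j y_i y_j K_ij - sum_i a_i
//   s.t. 0 <= a_i <= C,  sum_i a_i y_i = 0.
// Maximal-violating-pair working-set selection on the precomputed kernel
// matrix, as in standard SMO implementations. F_t = sum_s a_s y_s K_st - y_t,
// so the KKT gap is max_{I_up}(-F) - min_{I_low}(-F).
// [[Rcpp::export]]
List smo_solve(const NumericMatrix& K, const NumericVector& y, double C,
               double tol = 1e-3, int max_iter = 100000) {
  const int m = K.nrow();
  NumericVector alpha(m, 0.0);
  std::vector<double> F(m);
  for (int t = 0; t < m; ++t) F[t] = -y[t];

  int iter = 0;
  double b = 0.0;
  for (; iter < max_iter; ++iter) {
    // select i = argmax_{I_up} -F_t, j = argmin_{I_low} -F_t
    int i = -1, j = -1;
    double up = -std::numeric_limits<double>::infinity();
    double low = std::numeric_limits<double>::infinity();
    for (int t = 0; t < m; ++t) {
      bool in_up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool in_low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      if (in_up && -F[t] > up) { up = -F[t]; i = t; }
      if (in_low && -F[t] < low) { low = -F[t]; j = t; }
    }
    if (i < 0 || j < 0 || up - low < tol) {
      b = (up + low) / 2.0;
      break;
    }
    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta < 1e-12) eta = 1e-12;
    double ai = alpha[i], aj = alpha[j];
    double aj_new = aj + y[j] * (F[i] - F[j]) / eta;
    double L, H;
    if (y[i] != y[j]) { L = std::max(0.0, aj - ai); H = std::min(C, C + aj - ai); }
    else              { L = std::max(0.0, ai + aj - C); H = std::min(C, ai + aj); }
    if (aj_new < L) aj_new = L;
    if (aj_new > H) aj_new = H;
    if (std::fabs(aj_new - aj) < 1e-14) {
      // numerically stuck pair: nudge the gradient bookkeeping and stop
      b = (up + low) / 2.0;
      break;
    }
    double ai_new = ai + y[i] * y[j] * (aj - aj_new);
    alpha[i] = ai_new;
    alpha[j] = aj_new;
    double di = y[i] * (ai_new - ai), dj = y[j] * (aj_new - aj);
    for (int t = 0; t < m; ++t) F[t] += di * K(i, t) + dj * K(j, t);
    b = (up + low) / 2.0;
  }
  return List::create(
    _["alpha"] = alpha, _["b"] = b, _["iterations"] = iter,
    _["converged"] = iter < max_iter);
}

// Squared Euclidean distances between the rows of A (ma x n) and B (mb x n).
// [[Rcpp::export]]
NumericMatrix row_sq_dist(const NumericMatrix& A, const NumericMatrix& B) {
  const int ma = A.nrow(), mb = B.nrow(), n = A.ncol();
  NumericMatrix D(ma, mb);
  for (int i = 0; i < ma; ++i) {
    for (int j = 0; j < mb; ++j) {
      double s = 0.0;
      for (int k = 0; k < n; ++k) {
        double d = A(i, k) - B(j, k);
        s += d * d;
      }
      D(i, j) = s;
    }
  }
  return D;
}
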