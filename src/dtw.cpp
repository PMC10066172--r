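#include <Rcpp.h>
using namespace Rcpp;

// Dynamic time warping between two univariate series, |a_i - b_j| local
// cost, monotone step patterns:
//   step == 1 (symmetric1): D[i][j] = c + min(D[i-1][j], D[i][j-1], D[i-1][j-1])
//   step == 2 (symmetric2): D[i][j] = min(D[i-1][j] + c, D[i][j-1] + c,
//                                         D[i-1][j-1] + 2c)
// window < 0 disables the Sakoe-Chiba band. Two rolling rows keep memory
// at O(m).
static double dtw_core(const NumericVector& a, const NumericVector& b,
                       int step, int window) {
  const int n = a.size(), m = b.size();
  const double inf = R_PosInf;
  std::vector<double> prev(m + 1, inf), cur(m + 1, inf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), inf);
    int jlo = 1, jhi = m;
    if (window >= 0) {
      jlo = std::max(1, i - window);
      jhi = std::min(m, i + window);
    }
    for (int j = jlo; j <= jhi; ++j) {
      const double c = std::abs(a[i - 1] - b[j - 1]);
      double best;
      if (step == 1) {
        best = std::min(prev[j], std::min(cur[j - 1], prev[j - 1])) + c;
      } else {
        best = std::min(prev[j] + c,
                        std::min(cur[j - 1] + c, prev[j - 1] + 2.0 * c));
      }
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
double dtw_distance_cpp(NumericVector a, NumericVector b, int step,
                        int window) {
  return dtw_core(a, b, step, window);
}

// [[Rcpp::export]]
NumericMatrix dtw_matrix_cpp(List series, int step, int window) {
  const int n = series.size();
  std::vector<NumericVector> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<NumericVector>(series[i]);
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double d = dtw_core(s[i], s[j], step, window);
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}
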