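#include <Rcpp.h>
using namespace Rcpp;

// Classic dynamic time warping: |a_i - b_j| local cost, symmetric step
// pattern (diagonal, up, left), full DP, no warping window.

// [[Rcpp::export(name = ".dtw_cpp")]]
double dtw_cpp(const NumericVector &a, const NumericVector &b) {
  int n = a.size(), m = b.size();
  std::vector<double> prev(m + 1, R_PosInf), cur(m + 1, R_PosInf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = R_PosInf;
    for (int j = 1; j <= m; ++j) {
      double c = std::abs(a[i - 1] - b[j - 1]);
      double best = std::min(prev[j - 1], std::min(prev[j], cur[j - 1]));
      cur[j] = c + best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
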