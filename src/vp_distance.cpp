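#include <Rcpp.h>
using namespace Rcpp;

// Victor-Purpura spike-train edit distance by dynamic programming over the
// (nA+1) x (nB+1) cost matrix: insertions/deletions cost 1, shifting a spike
// by dt costs q * |dt| (q in 1/ms, times in ms).
//
// [[Rcpp::export]]
double vp_distance_cpp(NumericVector a, NumericVector b, double q) {
  const int na = a.size(), nb = b.size();
  std::vector<double> prev(nb + 1), cur(nb + 1);
  for (int j = 0; j <= nb; ++j) prev[j] = j;
  for (int i = 1; i <= na; ++i) {
    cur[0] = i;
    for (int j = 1; j <= nb; ++j) {
      const double shift = prev[j - 1] + q * std::fabs(a[i - 1] - b[j - 1]);
      const double del = prev[j] + 1.0;
      const double ins = cur[j - 1] + 1.0;
      cur[j] = std::min(shift, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[nb];
}
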