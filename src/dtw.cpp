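#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Unconstrained subsequence DTW (SPRING-style) of a template y against a
// signal x with absolute-difference local cost and symmetric steps
// (diagonal, up, left). For every signal index j it returns the accumulated
// cost of the best warping path ending at (m-1, j), normalized by the
// template length, together with the 0-based signal index where that path
// starts. Match-length (warping) constraints are applied by the caller.
// [[Rcpp::export]]
List subsequence_dtw(NumericVector x, NumericVector y) {
  const int n = x.size(), m = y.size();
  if (n == 0 || m == 0) stop("subsequence_dtw: empty input");
  std::vector<double> prev(n), cur(n);
  std::vector<int> sprev(n), scur(n);
  for (int j = 0; j < n; ++j) {
    prev[j] = std::fabs(y[0] - x[j]);
    sprev[j] = j;
  }
  for (int i = 1; i < m; ++i) {
    cur[0] = prev[0] + std::fabs(y[i] - x[0]);
    scur[0] = sprev[0];
    for (int j = 1; j < n; ++j) {
      double best = prev[j - 1];
      int sb = sprev[j - 1];
      if (prev[j] < best) { best = prev[j]; sb = sprev[j]; }
      if (cur[j - 1] < best) { best = cur[j - 1]; sb = scur[j - 1]; }
      cur[j] = best + std::fabs(y[i] - x[j]);
      scur[j] = sb;
    }
    prev.swap(cur);
    sprev.swap(scur);
  }
  NumericVector cost(n);
  IntegerVector start(n);
  for (int j = 0; j < n; ++j) {
    cost[j] = prev[j] / m;
    start[j] = sprev[j];
  }
  return List::create(_["cost"] = cost, _["start"] = start);
}
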