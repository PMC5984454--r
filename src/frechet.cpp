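#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Discrete Frechet distance between two polylines given as n x 2 matrices
// (columns: temperature, heat capacity). Standard coupling-lattice dynamic
// program: c(i,j) = max(||A_i - B_j||, min(c(i-1,j), c(i,j-1), c(i-1,j-1))).
// Two rolling rows keep memory at O(ncol) for 451-point curves.
// [[Rcpp::export]]
double frechet_dp(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  if (n < 1 || m < 1) stop("curves must contain at least one point");
  std::vector<double> prev(m), curr(m);
  for (int i = 0; i < n; ++i) {
    const double ax = A(i, 0), ay = A(i, 1);
    for (int j = 0; j < m; ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1);
      const double d = std::sqrt(dx * dx + dy * dy);
      double reach;
      if (i == 0 && j == 0) {
        reach = d;
      } else if (i == 0) {
        reach = std::max(curr[j - 1], d);
      } else if (j == 0) {
        reach = std::max(prev[0], d);
      } else {
        reach = std::max(std::min(prev[j], std::min(curr[j - 1], prev[j - 1])), d);
      }
      curr[j] = reach;
    }
    std::swap(prev, curr);
  }
  return prev[m - 1];
}
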