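#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Per-row rank-sum statistics for a genes x cells matrix whose first na
// columns are group A. Returns, per row, the Mann-Whitney U for group A
// (rank sum minus na(na+1)/2, midranks for ties), the tie-correction term
// sum(t^3 - t), and whether any tie is present. The p-value is computed in R
// with the same normal approximation (tie + continuity corrected) used by
// the scalar test.
// [[Rcpp::export]]
List rank_sum_rows_cpp(NumericMatrix x, int na) {
  const int g = x.nrow();
  const int n = x.ncol();
  if (na < 1 || na >= n) stop("invalid group split");
  NumericVector U(g), tiesum(g);
  LogicalVector has_ties(g);
  std::vector<int> ord(n);
  std::vector<double> ranks(n);

  for (int i = 0; i < g; ++i) {
    for (int k = 0; k < n; ++k) ord[k] = k;
    NumericMatrix::Row row = x(i, _);
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return row[a] < row[b]; });
    double ts = 0.0;
    bool ties = false;
    int k = 0;
    while (k < n) {
      int j = k;
      while (j + 1 < n && row[ord[j + 1]] == row[ord[k]]) ++j;
      const double t = j - k + 1;
      const double mid = (k + j) / 2.0 + 1.0;  // average rank, 1-based
      for (int m = k; m <= j; ++m) ranks[ord[m]] = mid;
      if (t > 1) { ties = true; ts += t * t * t - t; }
      k = j + 1;
    }
    double rs = 0.0;
    for (int m = 0; m < na; ++m) rs += ranks[m];
    U[i] = rs - na * (na + 1.0) / 2.0;
    tiesum[i] = ts;
    has_ties[i] = ties;
  }
  return List::create(_["U"] = U, _["tiesum"] = tiesum,
                      _["has_ties"] = has_ties);
}
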