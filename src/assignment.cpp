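#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Jonker-Volgenant / Hungarian algorithm (shortest augmenting path form).
// Solves the rectangular assignment problem for a cost matrix with
// nrow <= ncol; every row is assigned to a distinct column minimizing the
// total cost. Deterministic for identical inputs.
//
// Returns a 1-based column index per row.
// [[Rcpp::export(name = ".solve_lsap_cpp")]]
IntegerVector solve_lsap_cpp(NumericMatrix cost) {
  const int n = cost.nrow();
  const int m = cost.ncol();
  if (n > m) stop("cost matrix must have nrow <= ncol");
  const double INF = std::numeric_limits<double>::infinity();

  std::vector<double> u(n + 1, 0.0), v(m + 1, 0.0);
  std::vector<int> p(m + 1, 0), way(m + 1, 0);

  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(m + 1, INF);
    std::vector<bool> used(m + 1, false);
    do {
      used[j0] = true;
      int i0 = p[j0], j1 = 0;
      double delta = INF;
      for (int j = 1; j <= m; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= m; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else          minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }

  IntegerVector ans(n);
  for (int j = 1; j <= m; ++j) {
    if (p[j] > 0) ans[p[j] - 1] = j;
  }
  return ans;
}
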