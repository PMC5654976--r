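#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact minimizer of sum_k T_k(j_k, j_{k+1}) over a cyclic chain of
// candidate selections, where table k holds the quad area between every
// candidate on spoke k (rows) and every candidate on spoke k+1 (columns),
// indices cyclic. The cycle is closed by conditioning on spoke 0's
// candidate: for each such candidate a backward dynamic program over the
// open chain gives the optimal completion; the best conditioning wins.
// Ties resolve to the lexicographically smallest index vector (candidates
// of spoke 0 are tried in ascending order and the forward reconstruction
// always takes the smallest index attaining the optimum).
//
// Complexity O(n * m^2 * m0) time, O(n * m^2) memory. Tables are copied
// into row-major buffers so the inner minimization runs over contiguous
// memory.

// [[Rcpp::export]]
List dp_cyclic_core(List tables) {
  const int n = tables.size();
  if (n < 2) stop("need at least 2 cost tables");
  std::vector<std::vector<double>> T(n);  // row-major
  std::vector<int> m(n);
  for (int k = 0; k < n; ++k) {
    NumericMatrix Tk = as<NumericMatrix>(tables[k]);
    if (Tk.nrow() == 0 || Tk.ncol() == 0)
      stop("empty candidate set in cost table %d", k + 1);
    m[k] = Tk.nrow();
    const int nc = Tk.ncol();
    T[k].resize((size_t)m[k] * nc);
    for (int j = 0; j < m[k]; ++j)
      for (int l = 0; l < nc; ++l)
        T[k][(size_t)j * nc + l] = Tk(j, l);
  }
  std::vector<int> ncols(n);
  for (int k = 0; k < n; ++k) {
    int nxt = (k + 1) % n;
    ncols[k] = (int)(T[k].size() / m[k]);
    if (ncols[k] != m[nxt])
      stop("cost table %d has %d columns but spoke %d has %d candidates",
           k + 1, ncols[k], nxt + 1, m[nxt]);
  }

  const int m0 = m[0];
  double best_total = R_PosInf;
  IntegerVector best_sel(n);

  // g[k][j]: minimal cost of edges k..n-1 starting from candidate j on
  // spoke k and ending at the conditioning candidate c0 on spoke 0.
  std::vector<std::vector<double>> g(n);
  for (int k = 1; k < n; ++k) g[k].assign(m[k], 0.0);
  std::vector<int> sel(n);

  for (int c0 = 0; c0 < m0; ++c0) {
    {
      const std::vector<double>& Tl = T[n - 1];
      const int nc = ncols[n - 1];
      for (int j = 0; j < m[n - 1]; ++j) g[n - 1][j] = Tl[(size_t)j * nc + c0];
    }
    for (int k = n - 2; k >= 1; --k) {
      const std::vector<double>& Tk = T[k];
      const int nc = ncols[k];
      const std::vector<double>& gn = g[k + 1];
      for (int j = 0; j < m[k]; ++j) {
        const double* row = &Tk[(size_t)j * nc];
        double bestv = R_PosInf;
        for (int l = 0; l < nc; ++l) {
          double v = row[l] + gn[l];
          if (v < bestv) bestv = v;
        }
        g[k][j] = bestv;
      }
    }
    double total = R_PosInf;
    {
      const double* row = &T[0][(size_t)c0 * ncols[0]];
      const std::vector<double>& g1 = g[1];
      for (int l = 0; l < ncols[0]; ++l) {
        double v = row[l] + g1[l];
        if (v < total) total = v;
      }
    }
    if (total < best_total) {
      sel[0] = c0;
      int prev = c0;
      for (int k = 1; k < n; ++k) {
        const double* row = &T[k - 1][(size_t)prev * ncols[k - 1]];
        const std::vector<double>& gk = g[k];
        double bestv = R_PosInf;
        int arg = 0;
        for (int l = 0; l < m[k]; ++l) {
          double v = row[l] + gk[l];
          if (v < bestv) { bestv = v; arg = l; }
        }
        sel[k] = arg;
        prev = arg;
      }
      best_total = total;
      for (int k = 0; k < n; ++k) best_sel[k] = sel[k] + 1;  // 1-based
    }
  }

  return List::create(_["indices"] = best_sel, _["total"] = best_total);
}
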