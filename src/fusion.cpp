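#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// Max-weight bipartite matching over strictly positive weights by bitmask DP
// (smaller side as the mask). Rows/cols with no positive weight cost nothing.
// w: n1 x n2, entries <= 0 mean "no link".
double matching_value(const NumericMatrix& w, const std::vector<int>& rows,
                      const std::vector<int>& cols) {
  const int n1 = (int)rows.size(), n2 = (int)cols.size();
  if (n1 == 0 || n2 == 0) return 0.0;
  if (n2 > 20) Rcpp::stop("matching side too large for exact solver");
  const int full = 1 << n2;
  std::vector<double> dp(full, 0.0), ndp(full);
  for (int i = 0; i < n1; ++i) {
    ndp = dp;
    for (int mask = 0; mask < full; ++mask) {
      const double base = dp[mask];
      for (int j = 0; j < n2; ++j) {
        if (mask & (1 << j)) continue;
        const double wij = w(rows[i], cols[j]);
        if (wij <= 0) continue;
        const int nm = mask | (1 << j);
        const double cand = base + wij;
        if (cand > ndp[nm]) ndp[nm] = cand;
      }
    }
    dp.swap(ndp);
  }
  double best = 0.0;
  for (int mask = 0; mask < full; ++mask) if (dp[mask] > best) best = dp[mask];
  return best;
}

} // namespace

// Matching values for every antichain pair: acA / acB are lists of 1-based
// node index vectors into the rows / columns of w.
// [[Rcpp::export]]
NumericMatrix cpp_matching_values(const NumericMatrix& w, const List& acA,
                                  const List& acB) {
  const int A = acA.size(), B = acB.size();
  NumericMatrix out(A, B);
  std::vector<std::vector<int>> rows(A), cols(B);
  for (int a = 0; a < A; ++a) {
    IntegerVector v = acA[a];
    rows[a].assign(v.begin(), v.end());
    for (auto& x : rows[a]) --x;
  }
  for (int b = 0; b < B; ++b) {
    IntegerVector v = acB[b];
    cols[b].assign(v.begin(), v.end());
    for (auto& x : cols[b]) --x;
  }
  for (int a = 0; a < A; ++a)
    for (int b = 0; b < B; ++b)
      out(a, b) = matching_value(w, rows[a], cols[b]);
  return out;
}

// Max-weight matching with pair recovery (used to materialise the links of
// the optimal solution). Returns value and matched (row, col) 1-based pairs.
// [[Rcpp::export]]
List cpp_max_matching(const NumericMatrix& w) {
  const int n1 = w.nrow(), n2 = w.ncol();
  if (n2 > 20) Rcpp::stop("matching side too large for exact solver");
  const int full = 1 << n2;
  // dp[i][mask]: best over first i rows with cols in mask used
  std::vector<std::vector<double>> dp(n1 + 1,
                                      std::vector<double>(full, 0.0));
  for (int i = 0; i < n1; ++i) {
    dp[i + 1] = dp[i];
    for (int mask = 0; mask < full; ++mask) {
      const double base = dp[i][mask];
      for (int j = 0; j < n2; ++j) {
        if (mask & (1 << j)) continue;
        const double wij = w(i, j);
        if (wij <= 0) continue;
        const int nm = mask | (1 << j);
        if (base + wij > dp[i + 1][nm]) dp[i + 1][nm] = base + wij;
      }
    }
  }
  int best_mask = 0;
  double best = 0.0;
  for (int mask = 0; mask < full; ++mask)
    if (dp[n1][mask] > best) { best = dp[n1][mask]; best_mask = mask; }
  // backtrack
  std::vector<int> ri, ci;
  int mask = best_mask;
  for (int i = n1; i >= 1; --i) {
    if (dp[i][mask] == dp[i - 1][mask]) continue;
    bool found = false;
    for (int j = 0; j < n2 && !found; ++j) {
      if (!(mask & (1 << j))) continue;
      const double wij = w(i - 1, j);
      if (wij <= 0) continue;
      if (std::abs(dp[i][mask] - (dp[i - 1][mask ^ (1 << j)] + wij)) < 1e-12) {
        ri.push_back(i);
        ci.push_back(j + 1);
        mask ^= (1 << j);
        found = true;
      }
    }
  }
  IntegerMatrix pairs(ri.size(), 2);
  for (size_t k = 0; k < ri.size(); ++k) {
    pairs(k, 0) = ri[ri.size() - 1 - k];
    pairs(k, 1) = ci[ri.size() - 1 - k];
  }
  return List::create(_["value"] = best, _["pairs"] = pairs);
}
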