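#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Pairwise Euclidean distances between rows of x (points in rows).
// [[Rcpp::export]]
NumericMatrix cpp_pairwise_dist(const NumericMatrix& x) {
  const int n = x.nrow(), d = x.ncol();
  NumericMatrix out(n, n);
  // column-major traversal: accumulate squared differences one dim at a time
  std::vector<double> acc((size_t)n * n, 0.0);
  for (int k = 0; k < d; ++k) {
    const double* col = &x(0, k);
    for (int j = 0; j < n; ++j) {
      const double xj = col[j];
      double* accj = &acc[(size_t)j * n];
      for (int i = j + 1; i < n; ++i) {
        const double diff = col[i] - xj;
        accj[i] += diff * diff;
      }
    }
  }
  for (int j = 0; j < n; ++j)
    for (int i = j + 1; i < n; ++i) {
      const double v = std::sqrt(acc[(size_t)j * n + i]);
      out(i, j) = v;
      out(j, i) = v;
    }
  return out;
}

namespace {

// xoshiro256+ with splitmix64 seeding; seeded from R's RNG per sweep so the
// whole clustering remains reproducible through set.seed()
struct FastRng {
  uint64_t s[4];
  explicit FastRng(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = s[0] + s[3];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
};

struct DSU {
  std::vector<int> parent, rank_;
  explicit DSU(int n) : parent(n), rank_(n, 0) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (rank_[a] < rank_[b]) std::swap(a, b);
    parent[b] = a;
    if (rank_[a] == rank_[b]) ++rank_[a];
  }
  void reset() {
    for (size_t i = 0; i < parent.size(); ++i) { parent[i] = (int)i; rank_[i] = 0; }
  }
};

// Interaction graph: union of the mutual K-nearest-neighbour graph and the
// Euclidean minimum spanning tree (the MST guarantees connectivity so that
// the zero-temperature partition is a single cluster).
void build_graph(const NumericMatrix& dist, int K,
                 std::vector<int>& ei, std::vector<int>& ej,
                 std::vector<double>& ed) {
  const int n = dist.nrow();
  const int Keff = std::min(K, n - 1);
  std::vector<std::vector<int>> nbr(n);
  for (int i = 0; i < n; ++i) {
    std::vector<int> idx;
    idx.reserve(n - 1);
    for (int j = 0; j < n; ++j) if (j != i) idx.push_back(j);
    std::partial_sort(idx.begin(), idx.begin() + Keff, idx.end(),
                      [&](int a, int b) { return dist(i, a) < dist(i, b); });
    nbr[i].assign(idx.begin(), idx.begin() + Keff);
    std::sort(nbr[i].begin(), nbr[i].end());
  }
  std::vector<std::vector<bool>> in_edge(n);
  for (int i = 0; i < n; ++i) in_edge[i].assign(n, false);
  // mutual KNN
  for (int i = 0; i < n; ++i)
    for (int j : nbr[i])
      if (j > i && std::binary_search(nbr[j].begin(), nbr[j].end(), i))
        in_edge[i][j] = true;
  // Prim's MST on the full distance matrix
  std::vector<bool> used(n, false);
  std::vector<double> best(n, R_PosInf);
  std::vector<int> from(n, -1);
  used[0] = true;
  for (int j = 1; j < n; ++j) { best[j] = dist(0, j); from[j] = 0; }
  for (int it = 1; it < n; ++it) {
    int v = -1;
    double bv = R_PosInf;
    for (int j = 0; j < n; ++j)
      if (!used[j] && best[j] < bv) { bv = best[j]; v = j; }
    if (v < 0) break;
    used[v] = true;
    int a = std::min(v, from[v]), b = std::max(v, from[v]);
    in_edge[a][b] = true;
    for (int j = 0; j < n; ++j)
      if (!used[j] && dist(v, j) < best[j]) { best[j] = dist(v, j); from[j] = v; }
  }
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (in_edge[i][j]) {
        ei.push_back(i); ej.push_back(j); ed.push_back(dist(i, j));
      }
}

} // namespace

// Superparamagnetic clustering sweep: q-state Potts model with
// Swendsen-Wang updates on the mutual-KNN + MST interaction graph.
// Returns a label matrix [temperatures x points]; points sharing a label at
// a temperature have spin-spin correlation > corr_threshold there.
// Uses R's RNG (seed via set.seed()).
// [[Rcpp::export]]
IntegerMatrix cpp_spc_sweep(const NumericMatrix& dist, const NumericVector& temps,
                            int q, int K, int sweeps, int burnin,
                            double corr_threshold) {
  const int n = dist.nrow();
  const int nt = temps.size();
  IntegerMatrix labels(nt, n);
  if (n == 1) return labels;

  std::vector<int> ei, ej;
  std::vector<double> ed;
  build_graph(dist, K, ei, ej, ed);
  const int m = (int)ei.size();

  // local length scale: mean nearest-neighbour distance
  double a_scale = 0.0;
  for (int i = 0; i < n; ++i) {
    double mn = R_PosInf;
    for (int j = 0; j < n; ++j)
      if (j != i && dist(i, j) < mn) mn = dist(i, j);
    a_scale += mn;
  }
  a_scale /= n;
  const double khat = 2.0 * m / n;
  std::vector<double> J(m);
  for (int e = 0; e < m; ++e) {
    if (a_scale > 0.0)
      J[e] = std::exp(-(ed[e] * ed[e]) / (2.0 * a_scale * a_scale)) / khat;
    else
      // coincident points interact infinitely strongly
      J[e] = (ed[e] == 0.0) ? 1e6 : 0.0;
  }

  std::vector<int> spin(n), comp_spin(n);
  std::vector<double> same_count(m);
  DSU dsu(n);
  RNGScope scope;
  FastRng rng((uint64_t)(unif_rand() * 9007199254740992.0) ^
              ((uint64_t)(unif_rand() * 9007199254740992.0) << 11));

  for (int t = 0; t < nt; ++t) {
    const double T = temps[t];
    std::vector<double> pfreeze(m);
    for (int e = 0; e < m; ++e)
      pfreeze[e] = (T <= 0.0) ? 1.0 : 1.0 - std::exp(-J[e] / T);
    // ordered start: the equilibrium state at T = 0, disorders quickly at
    // high T, avoids slow coarsening from a random start at low T
    std::fill(spin.begin(), spin.end(), 0);
    std::fill(same_count.begin(), same_count.end(), 0.0);
    const int total = burnin + sweeps;
    for (int s = 0; s < total; ++s) {
      dsu.reset();
      for (int e = 0; e < m; ++e)
        if (spin[ei[e]] == spin[ej[e]] &&
            (pfreeze[e] >= 1.0 || rng.unif() < pfreeze[e]))
          dsu.unite(ei[e], ej[e]);
      for (int i = 0; i < n; ++i) comp_spin[i] = -1;
      for (int i = 0; i < n; ++i) {
        const int r = dsu.find(i);
        if (comp_spin[r] < 0)
          comp_spin[r] = (int)(rng.next() % (uint64_t)q);
        spin[i] = comp_spin[r];
      }
      if (s >= burnin)
        for (int e = 0; e < m; ++e)
          if (spin[ei[e]] == spin[ej[e]]) same_count[e] += 1.0;
    }
    // link edges whose average spin agreement exceeds the threshold,
    // label connected components
    dsu.reset();
    for (int e = 0; e < m; ++e)
      if (same_count[e] / sweeps > corr_threshold)
        dsu.unite(ei[e], ej[e]);
    std::vector<int> lbl(n, -1);
    int next = 0;
    for (int i = 0; i < n; ++i) {
      const int r = dsu.find(i);
      if (lbl[r] < 0) lbl[r] = next++;
      labels(t, i) = lbl[r];
    }
  }
  return labels;
}
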