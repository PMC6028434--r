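#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Exact randomized control centrality.
//
// C_c(i) is the generic dimension of the controllable subspace of the
// structured system (A, e_i), i.e. the generic rank of the Krylov matrix
// [b, Ab, ..., A^{N-1}b]. Random edge weights over GF(p), p = 2^31 - 1,
// give that rank with failure probability <= (N/p) per trial
// (Schwartz-Zippel); the maximum over trials is reported. All arithmetic is
// exact, so there is no floating-point rank tolerance.

static const uint64_t GFP = 2147483647ULL; // 2^31 - 1, prime

struct XorShift64 {
  uint64_t s;
  explicit XorShift64(uint64_t seed) {
    // splitmix64 scramble so small seeds give well-mixed states
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s = z ^ (z >> 31);
    if (s == 0) s = 0x106689D45497FDB5ULL;
  }
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  // uniform in [1, p-1]
  uint64_t weight() { return 1 + next() % (GFP - 1); }
};

// reduce v against a basis kept in reduced form (pivot value 1);
// returns pivot index or -1 when v reduces to zero
static int reduce_against(std::vector<uint64_t>& v,
                          const std::vector<std::vector<uint64_t> >& basis,
                          const std::vector<int>& pivots) {
  const int n = (int)v.size();
  for (size_t k = 0; k < basis.size(); ++k) {
    uint64_t c = v[pivots[k]];
    if (c == 0) continue;
    const std::vector<uint64_t>& b = basis[k];
    for (int j = 0; j < n; ++j) {
      if (b[j]) v[j] = (v[j] + (GFP - c) * b[j]) % GFP;
    }
  }
  for (int j = 0; j < n; ++j) if (v[j]) return j;
  return -1;
}

static uint64_t powmod(uint64_t a, uint64_t e) {
  uint64_t r = 1;
  a %= GFP;
  while (e) {
    if (e & 1ULL) r = r * a % GFP;
    a = a * a % GFP;
    e >>= 1;
  }
  return r;
}

// [[Rcpp::export]]
IntegerVector cc_krylov_cpp(int n, IntegerVector from0, IntegerVector to0,
                            IntegerVector starts0, int n_trials, double seed) {
  const int m = from0.size();
  const int ns = starts0.size();
  std::vector<int> best(ns, 0);
  XorShift64 rng((uint64_t)seed);

  for (int trial = 0; trial < n_trials; ++trial) {
    std::vector<uint64_t> w(m);
    for (int e = 0; e < m; ++e) w[e] = rng.weight();

    for (int si = 0; si < ns; ++si) {
      int s = starts0[si];
      std::vector<uint64_t> kry(n, 0);
      kry[s] = 1; // b = e_s (a generic b weight only rescales the space)
      std::vector<std::vector<uint64_t> > basis;
      std::vector<int> pivots;
      int rank = 0;
      for (int it = 0; it < n; ++it) {
        std::vector<uint64_t> v(kry);
        int piv = reduce_against(v, basis, pivots);
        if (piv < 0) break; // Krylov space is now A-invariant
        uint64_t inv = powmod(v[piv], GFP - 2);
        for (int j = 0; j < n; ++j) if (v[j]) v[j] = v[j] * inv % GFP;
        basis.push_back(v);
        pivots.push_back(piv);
        ++rank;
        if (rank == n) break;
        std::vector<uint64_t> nx(n, 0);
        for (int e = 0; e < m; ++e) {
          uint64_t x = kry[from0[e]];
          if (x) nx[to0[e]] = (nx[to0[e]] + w[e] * x) % GFP;
        }
        kry.swap(nx);
      }
      if (rank > best[si]) best[si] = rank;
    }
  }
  return IntegerVector(best.begin(), best.end());
}

// Brute-force combinatorial oracle: C_c(i) = 1 + the maximum number of
// state-graph edges over vertex-disjoint unions of one directed path
// starting at i and directed cycles, all inside the set reachable from i.
// Bitmask DP: path states P[mask] = endpoints reachable using exactly
// `mask`; g[mask] = most vertices coverable by disjoint cycles inside
// `mask` (a cycle of length L contributes L edges = L vertices).

// [[Rcpp::export]]
int cc_stemcycle_cpp(int n, IntegerVector from0, IntegerVector to0,
                     int start0) {
  const int m_edges = from0.size();
  std::vector<std::vector<int> > out(n);
  for (int e = 0; e < m_edges; ++e) out[from0[e]].push_back(to0[e]);

  // reachable set from start
  std::vector<char> inR(n, 0);
  std::vector<int> stack(1, start0);
  inR[start0] = 1;
  while (!stack.empty()) {
    int u = stack.back(); stack.pop_back();
    for (size_t k = 0; k < out[u].size(); ++k) {
      int v = out[u][k];
      if (!inR[v]) { inR[v] = 1; stack.push_back(v); }
    }
  }
  std::vector<int> idx(n, -1), verts;
  for (int v = 0; v < n; ++v) if (inR[v]) { idx[v] = verts.size(); verts.push_back(v); }
  const int m = (int)verts.size();
  if (m > 22) stop("stem-cycle oracle limited to <= 22 reachable vertices");
  std::vector<uint32_t> adj(m, 0);
  for (int e = 0; e < m_edges; ++e)
    if (inR[from0[e]] && inR[to0[e]] && from0[e] != to0[e])
      adj[idx[from0[e]]] |= (1u << idx[to0[e]]);
  const int s = idx[start0];
  const uint32_t FULL = (m == 32) ? 0xFFFFFFFFu : ((1u << m) - 1u);

  // enumerate simple cycles, canonical root = minimum-index vertex
  std::vector<std::vector<uint32_t> > cycByMin(m);
  for (int r = 0; r < m; ++r) {
    // DFS over paths r -> v using only vertices > r
    std::vector<std::pair<int, uint32_t> > st;
    st.push_back(std::make_pair(r, (uint32_t)(1u << r)));
    while (!st.empty()) {
      int v = st.back().first;
      uint32_t mask = st.back().second;
      st.pop_back();
      if (v != r || mask != (uint32_t)(1u << r)) {
        if (adj[v] & (1u << r)) {
          if (mask != (uint32_t)(1u << r)) cycByMin[r].push_back(mask);
        }
      }
      for (int t = r + 1; t < m; ++t) {
        if ((adj[v] & (1u << t)) && !(mask & (1u << t)))
          st.push_back(std::make_pair(t, mask | (1u << t)));
      }
    }
  }

  const size_t NM = (size_t)1u << m;
  // cycle-cover DP
  std::vector<int> g(NM, 0);
  for (uint32_t mask = 1; mask < NM; ++mask) {
    int low = __builtin_ctz(mask);
    int bestv = g[mask & (mask - 1)]; // leave `low` uncovered
    const std::vector<uint32_t>& cyc = cycByMin[low];
    for (size_t k = 0; k < cyc.size(); ++k) {
      uint32_t c = cyc[k];
      if ((c & mask) == c) {
        int cand = __builtin_popcount(c) + g[mask & ~c];
        if (cand > bestv) bestv = cand;
      }
    }
    g[mask] = bestv;
  }

  // path DP from s
  std::vector<uint32_t> P(NM, 0);
  P[1u << s] = (1u << s);
  int best = 0;
  for (uint32_t mask = 1; mask < NM; ++mask) {
    if (!(mask & (1u << s))) continue;
    uint32_t ends = P[mask];
    if (!ends) continue;
    int plen = __builtin_popcount(mask) - 1;
    int cand = plen + g[FULL & ~mask];
    if (cand > best) best = cand;
    while (ends) {
      int v = __builtin_ctz(ends);
      ends &= ends - 1;
      uint32_t nxt = adj[v] & ~mask;
      while (nxt) {
        int t = __builtin_ctz(nxt);
        nxt &= nxt - 1;
        P[mask | (1u << t)] |= (1u << t);
      }
    }
  }
  return 1 + best; // the input edge u -> i is counted
}
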