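#include <Rcpp.h>
#include <unordered_set>
using namespace Rcpp;

// Degree-preserving pairwise edge swaps on parallel endpoint arrays
// (1-based node ids). Each of floor(q * m) attempts draws two distinct edges
// (u,v), (x,y), picks with equal probability the candidate pair {(u,y),(x,v)}
// or {(u,x),(v,y)}, and applies it only if neither candidate already exists
// or would be a self-loop. Weights stay attached to their edge slot, so the
// weight multiset is preserved. Uses R's RNG: seed via set.seed() upstream.
static void do_swaps(std::vector<int> &u, std::vector<int> &v,
                     int n_nodes, double q) {
  const int m = (int)u.size();
  if (m < 2 || q <= 0) return;
  const long long base = (long long)n_nodes + 1;
  auto key = [&](int a, int b) {
    if (a > b) std::swap(a, b);
    return (long long)a * base + b;
  };
  std::unordered_set<long long> seen;
  seen.reserve(m * 2);
  for (int i = 0; i < m; ++i) seen.insert(key(u[i], v[i]));

  const long long attempts = (long long)(q * (double)m);
  for (long long t = 0; t < attempts; ++t) {
    int i = (int)(unif_rand() * m);
    if (i >= m) i = m - 1;
    int j = i;
    while (j == i) {
      j = (int)(unif_rand() * m);
      if (j >= m) j = m - 1;
    }
    const int a = u[i], b = v[i], c = u[j], d = v[j];
    int a1, b1, a2, b2;
    if (unif_rand() < 0.5) { // (u,y), (x,v)
      a1 = a; b1 = d; a2 = c; b2 = b;
    } else {                 // (u,x), (v,y)
      a1 = a; b1 = c; a2 = b; b2 = d;
    }
    if (a1 == b1 || a2 == b2) continue;
    const long long k1 = key(a1, b1), k2 = key(a2, b2);
    if (k1 == k2) continue;
    if (seen.count(k1) || seen.count(k2)) continue;
    seen.erase(key(a, b));
    seen.erase(key(c, d));
    seen.insert(k1);
    seen.insert(k2);
    u[i] = a1; v[i] = b1;
    u[j] = a2; v[j] = b2;
  }
}

// [[Rcpp::export]]
List swap_edges_impl(IntegerVector from, IntegerVector to, int n_nodes, double q) {
  std::vector<int> u(from.begin(), from.end());
  std::vector<int> v(to.begin(), to.end());
  do_swaps(u, v, n_nodes, q);
  return List::create(
      Named("from") = IntegerVector(u.begin(), u.end()),
      Named("to") = IntegerVector(v.begin(), v.end()));
}

// One network-null replicate: rewire a copy of the network, then score every
// requested ordered pair. For source A the per-node contribution profile is
//   f[v]    = max over A-annotated neighbors u of w(u,v) * s(u),  v not in A
//   wmax[v] = max over A-annotated neighbors u of w(u,v)
// and the pair statistic is sum over v in N(A) and target B of
// s(v)*f[v] (minus sbar^2*wmax[v] per gene when normalizing).
// sets: list of 1-based member index vectors; pair_source/pair_target are
// 1-based indices into `sets`.
// [[Rcpp::export]]
NumericVector swap_and_score_impl(IntegerVector from, IntegerVector to,
                                  NumericVector weight, int n_nodes, double q,
                                  List sets, IntegerVector pair_source,
                                  IntegerVector pair_target, NumericVector s,
                                  double sbar, bool normalize) {
  std::vector<int> u(from.begin(), from.end());
  std::vector<int> v(to.begin(), to.end());
  do_swaps(u, v, n_nodes, q);

  const int m = (int)u.size();
  const int n_sets = sets.size();
  const int n_pairs = pair_source.size();
  std::vector<std::vector<char>> memb(n_sets, std::vector<char>(n_nodes + 1, 0));
  for (int k = 0; k < n_sets; ++k) {
    IntegerVector ids = sets[k];
    for (int i = 0; i < ids.size(); ++i) memb[k][ids[i]] = 1;
  }

  std::vector<double> f(n_nodes + 1, 0.0), wmax(n_nodes + 1, 0.0);
  std::vector<int> stamp(n_nodes + 1, -1);
  NumericVector stat(n_pairs);

  for (int k = 0; k < n_sets; ++k) {
    bool used = false;
    for (int p = 0; p < n_pairs; ++p)
      if (pair_source[p] - 1 == k) { used = true; break; }
    if (!used) continue;
    const std::vector<char> &in_a = memb[k];
    for (int e = 0; e < m; ++e) {
      for (int dir = 0; dir < 2; ++dir) {
        const int a = dir == 0 ? u[e] : v[e];
        const int b = dir == 0 ? v[e] : u[e];
        if (!in_a[a] || in_a[b]) continue;
        const double val = weight[e] * s[a - 1];
        if (stamp[b] != k) {
          stamp[b] = k;
          f[b] = val;
          wmax[b] = weight[e];
        } else {
          if (val > f[b]) f[b] = val;
          if (weight[e] > wmax[b]) wmax[b] = weight[e];
        }
      }
    }
    for (int p = 0; p < n_pairs; ++p) {
      if (pair_source[p] - 1 != k) continue;
      IntegerVector b_ids = sets[pair_target[p] - 1];
      double acc = 0.0, acc_bg = 0.0;
      for (int i = 0; i < b_ids.size(); ++i) {
        const int g = b_ids[i];
        if (stamp[g] != k) continue;
        acc += s[g - 1] * f[g];
        acc_bg += sbar * sbar * wmax[g];
      }
      stat[p] = normalize ? acc - acc_bg : acc;
    }
  }
  return stat;
}
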