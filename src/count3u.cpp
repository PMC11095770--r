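// Exact counting of simple 3-uniform (non-partite) hypergraph realizations
// of a degree sequence on n vertices, by include/exclude backtracking over
// the C(n,3) candidate triples.  Vertices are relabelled in non-increasing
// degree order so the highest-degree vertex's link is fixed first;
// candidates are visited lexicographically in the relabelled order.
// Pruning: every vertex's remaining degree must stay within [0, remaining
// incident candidates], and the total remaining degree must fit in the
// remaining candidates.
#include <Rcpp.h>
#include <array>
#include <vector>
using namespace Rcpp;

namespace {

struct Counter {
  int n, M;
  std::vector<std::array<int, 3>> tri;   // candidate triples
  std::vector<int> rem_deg;              // remaining degree per vertex
  std::vector<std::vector<int>> inc_after; // inc_after[v][t]: candidates >= t containing v
  long long sum_rem;
  long long count = 0;
  unsigned long long nodes = 0;

  bool feasible_at(int t) const {
    if (sum_rem > 3LL * (M - t)) return false;
    return true;
  }

  void rec(int t) {
    if ((++nodes & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    if (sum_rem == 0) {
      // all remaining candidates must be excluded; that is always allowed
      ++count;
      return;
    }
    if (t == M || !feasible_at(t)) return;
    const std::array<int, 3> &e = tri[t];
    // exclude candidate t: each of its vertices loses one incident candidate
    bool ok_ex = true;
    for (int v : e) if (rem_deg[v] > inc_after[v][t + 1]) { ok_ex = false; break; }
    // include candidate t
    bool ok_in = rem_deg[e[0]] > 0 && rem_deg[e[1]] > 0 && rem_deg[e[2]] > 0;
    if (ok_in) {
      for (int v : e) --rem_deg[v];
      sum_rem -= 3;
      bool ok = true;
      for (int v : e) if (rem_deg[v] > inc_after[v][t + 1]) { ok = false; break; }
      if (ok) rec(t + 1);
      for (int v : e) ++rem_deg[v];
      sum_rem += 3;
    }
    if (ok_ex) rec(t + 1);
  }
};

} // namespace

// [[Rcpp::export]]
double cpp_count_3uniform(IntegerVector degrees) {
  int n = degrees.size();
  if (n < 3) return 0.0;
  long long total = 0;
  for (int i = 0; i < n; ++i) total += degrees[i];
  if (total % 3 != 0) return 0.0;
  // relabel by non-increasing degree (stable)
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return degrees[a] > degrees[b]; });
  Counter cnt;
  cnt.n = n;
  cnt.rem_deg.resize(n);
  for (int i = 0; i < n; ++i) cnt.rem_deg[i] = degrees[ord[i]];
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b)
      for (int c = b + 1; c < n; ++c)
        cnt.tri.push_back({a, b, c});
  cnt.M = (int)cnt.tri.size();
  cnt.sum_rem = total;
  cnt.inc_after.assign(n, std::vector<int>(cnt.M + 1, 0));
  for (int t = cnt.M - 1; t >= 0; --t)
    for (int v = 0; v < n; ++v) {
      int in = (cnt.tri[t][0] == v || cnt.tri[t][1] == v || cnt.tri[t][2] == v);
      cnt.inc_after[v][t] = cnt.inc_after[v][t + 1] + in;
    }
  for (int v = 0; v < n; ++v)
    if (cnt.rem_deg[v] < 0 || cnt.rem_deg[v] > cnt.inc_after[v][0]) return 0.0;
  cnt.rec(0);
  return (double)cnt.count;
}
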