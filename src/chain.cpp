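// Metropolis and Parallel Tempering engines over tripartite 3-uniform
// hypergraph states.  A state lives on the hypercube {0,1}^(n1*n2*n3);
// moves are switches, hinge flips and toggles; the energy is the L1
// deviation of the current degree sequence from the prescribed one and is
// maintained incrementally.  All randomness flows through R's RNG so runs
// are reproducible under set.seed().
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

// change in |target - deg| when deg moves by delta (delta is +1 or -1)
inline int dev_bump(int deg, int target, int delta) {
  return std::abs(target - (deg + delta)) - std::abs(target - deg);
}

inline int runif_int(int n) {
  int r = (int)(unif_rand() * n);
  return r >= n ? n - 1 : r;
}

struct HGState {
  int n1, n2, n3, N;
  std::vector<char> present;      // cell -> 0/1
  std::vector<int> edges;         // edge list of cell ids
  std::vector<int> pos;           // cell -> index in edges, or -1
  std::vector<int> degA, degB, degC;
  const int *tA, *tB, *tC;        // prescribed degrees
  long energy;
  unsigned long mask = 0;         // occupancy bitmask (tiny N only)

  void init(int n1_, int n2_, int n3_,
            const int *tA_, const int *tB_, const int *tC_) {
    n1 = n1_; n2 = n2_; n3 = n3_; N = n1 * n2 * n3;
    tA = tA_; tB = tB_; tC = tC_;
    present.assign(N, 0);
    pos.assign(N, -1);
    edges.clear();
    degA.assign(n1, 0); degB.assign(n2, 0); degC.assign(n3, 0);
    energy = 0;
    for (int i = 0; i < n1; ++i) energy += std::abs(tA[i]);
    for (int j = 0; j < n2; ++j) energy += std::abs(tB[j]);
    for (int k = 0; k < n3; ++k) energy += std::abs(tC[k]);
  }

  inline void split(int cell, int &i, int &j, int &k) const {
    i = cell % n1; int r = cell / n1; j = r % n2; k = r / n2;
  }
  inline int cell_of(int i, int j, int k) const { return i + n1 * (j + n2 * k); }

  inline int delta_add(int cell) const {
    int i, j, k; split(cell, i, j, k);
    return dev_bump(degA[i], tA[i], 1) + dev_bump(degB[j], tB[j], 1) +
           dev_bump(degC[k], tC[k], 1);
  }
  inline int delta_remove(int cell) const {
    int i, j, k; split(cell, i, j, k);
    return dev_bump(degA[i], tA[i], -1) + dev_bump(degB[j], tB[j], -1) +
           dev_bump(degC[k], tC[k], -1);
  }

  void add_edge(int cell) {
    energy += delta_add(cell);
    int i, j, k; split(cell, i, j, k);
    ++degA[i]; ++degB[j]; ++degC[k];
    present[cell] = 1;
    pos[cell] = (int)edges.size();
    edges.push_back(cell);
    if (N <= 24) mask |= (1UL << cell);
  }
  void remove_edge(int cell) {
    energy += delta_remove(cell);
    int i, j, k; split(cell, i, j, k);
    --degA[i]; --degB[j]; --degC[k];
    present[cell] = 0;
    int p = pos[cell], last = (int)edges.size() - 1;
    if (p != last) { edges[p] = edges[last]; pos[edges[p]] = p; }
    edges.pop_back();
    pos[cell] = -1;
    if (N <= 24) mask &= ~(1UL << cell);
  }

  long recompute_energy() const {
    long e = 0;
    for (int i = 0; i < n1; ++i) e += std::abs(tA[i] - degA[i]);
    for (int j = 0; j < n2; ++j) e += std::abs(tB[j] - degB[j]);
    for (int k = 0; k < n3; ++k) e += std::abs(tC[k] - degC[k]);
    return e;
  }

  void set_edges(const IntegerMatrix &em) { // 0-based (i, j, k) rows
    for (int r = 0; r < em.nrow(); ++r)
      add_edge(cell_of(em(r, 0), em(r, 1), em(r, 2)));
  }
  IntegerMatrix get_edges() const {
    IntegerMatrix em((int)edges.size(), 3);
    for (int r = 0; r < (int)edges.size(); ++r) {
      int i, j, k; split(edges[r], i, j, k);
      em(r, 0) = i; em(r, 1) = j; em(r, 2) = k;
    }
    return em;
  }
};

// stats[kind][0..3]: proposed, invalid, accepted, rejected
// kind: 0 switch, 1 hinge flip, 2 toggle
struct OpStats { long s[3][4] = {{0}}; };

inline bool metro_accept(int dE, double T) {
  if (dE <= 0) return true;
  return log(unif_rand()) <= -((double)dE) / T;
}

// One Metropolis step of the single-temperature chain.  Invalid proposals
// are lazy self-loops: they advance the clock and leave the state alone.
void chain_step(HGState &st, double T, const double *w, OpStats &stats) {
  double u = unif_rand();
  int kind = (u < w[0]) ? 0 : (u < w[0] + w[1]) ? 1 : 2;
  long *s = stats.s[kind];
  ++s[0];
  int m = (int)st.edges.size();
  if (kind == 0) {                           // switch
    if (m == 0) { ++s[1]; return; }
    int e1 = st.edges[runif_int(m)];
    int e2 = st.edges[runif_int(m)];
    if (e1 == e2) { ++s[1]; return; }
    int cls = runif_int(3);
    int i1, j1, k1, i2, j2, k2;
    st.split(e1, i1, j1, k1); st.split(e2, i2, j2, k2);
    int f1, f2;
    if (cls == 0)      { f1 = st.cell_of(i2, j1, k1); f2 = st.cell_of(i1, j2, k2); }
    else if (cls == 1) { f1 = st.cell_of(i1, j2, k1); f2 = st.cell_of(i2, j1, k2); }
    else               { f1 = st.cell_of(i1, j1, k2); f2 = st.cell_of(i2, j2, k1); }
    if (st.present[f1] || st.present[f2]) { ++s[1]; return; }
    // degrees unchanged => dE = 0 => always accepted
    st.remove_edge(e1); st.remove_edge(e2);
    st.add_edge(f1); st.add_edge(f2);
    ++s[2];
  } else if (kind == 1) {                    // hinge flip
    if (m == 0) { ++s[1]; return; }
    int e = st.edges[runif_int(m)];
    int cls = runif_int(3);
    int i, j, k; st.split(e, i, j, k);
    int size = (cls == 0) ? st.n1 : (cls == 1) ? st.n2 : st.n3;
    if (size == 1) { ++s[1]; return; }
    int cur = (cls == 0) ? i : (cls == 1) ? j : k;
    int x = runif_int(size - 1);
    if (x >= cur) ++x;                       // uniform over the class minus cur
    int f = (cls == 0) ? st.cell_of(x, j, k)
          : (cls == 1) ? st.cell_of(i, x, k) : st.cell_of(i, j, x);
    if (st.present[f]) { ++s[1]; return; }
    int dE;
    if (cls == 0)      dE = dev_bump(st.degA[cur], st.tA[cur], -1) +
                            dev_bump(st.degA[x], st.tA[x], 1);
    else if (cls == 1) dE = dev_bump(st.degB[cur], st.tB[cur], -1) +
                            dev_bump(st.degB[x], st.tB[x], 1);
    else               dE = dev_bump(st.degC[cur], st.tC[cur], -1) +
                            dev_bump(st.degC[x], st.tC[x], 1);
    if (metro_accept(dE, T)) { st.remove_edge(e); st.add_edge(f); ++s[2]; }
    else ++s[3];
  } else {                                   // toggle in / out
    int cell = runif_int(st.N);
    if (st.present[cell]) {
      if (metro_accept(st.delta_remove(cell), T)) { st.remove_edge(cell); ++s[2]; }
      else ++s[3];
    } else {
      if (metro_accept(st.delta_add(cell), T)) { st.add_edge(cell); ++s[2]; }
      else ++s[3];
    }
  }
}

IntegerMatrix stats_matrix(const OpStats &st) {
  IntegerMatrix m(3, 4);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 4; ++j) m(i, j) = (int)st.s[i][j];
  m.attr("dimnames") = List::create(
      CharacterVector::create("switch", "hinge_flip", "toggle"),
      CharacterVector::create("proposed", "invalid", "accepted", "rejected"));
  return m;
}

} // namespace

// [[Rcpp::export]]
List cpp_run_chain(int n1, int n2, int n3, IntegerMatrix edges0,
                   IntegerVector tA, IntegerVector tB, IntegerVector tC,
                   double temperature, double n_steps, NumericVector weights,
                   int energy_every, int check_every, bool track_states) {
  HGState st;
  st.init(n1, n2, n3, tA.begin(), tB.begin(), tC.begin());
  st.set_edges(edges0);
  double w[3] = {weights[0], weights[1], weights[2]};
  OpStats stats;
  std::vector<double> trace, visits;
  if (track_states) {
    if (st.N > 20) stop("state tracking only supported for up to 20 cells");
    visits.assign(1UL << st.N, 0.0);
  }
  long long steps = (long long)n_steps;
  if (energy_every > 0) trace.reserve(steps / energy_every + 1);
  GetRNGstate();
  for (long long t = 1; t <= steps; ++t) {
    chain_step(st, temperature, w, stats);
    if (track_states) visits[st.mask] += 1.0;
    if (energy_every > 0 && t % energy_every == 0)
      trace.push_back((double)st.energy);
    if (check_every > 0 && t % check_every == 0 &&
        st.energy != st.recompute_energy()) {
      PutRNGstate();
      stop("incremental energy drifted from full recomputation");
    }
    if ((t & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  PutRNGstate();
  return List::create(_["edges"] = st.get_edges(),
                      _["energy"] = (double)st.energy,
                      _["stats"] = stats_matrix(stats),
                      _["energy_trace"] = NumericVector(trace.begin(), trace.end()),
                      _["state_visits"] = NumericVector(visits.begin(), visits.end()));
}

// Composite Parallel Tempering chain: with probability 1/2 a Metropolis
// step in one uniformly chosen member chain, otherwise a state-swap attempt
// at a uniformly chosen adjacent temperature pair.  Zero-energy states of
// the coldest chain are harvested once at least `spacing` coldest-chain
// proposals have elapsed since the previous harvest.
// [[Rcpp::export]]
List cpp_pt_run(int n1, int n2, int n3, List edges_list,
                IntegerVector tA, IntegerVector tB, IntegerVector tC,
                NumericVector temps, double n_steps, NumericVector weights,
                double spacing, int max_samples, bool harvest,
                int cold_energy_every, bool track_states) {
  int k = temps.size();
  if (edges_list.size() != k) stop("need one start state per temperature");
  std::vector<HGState> chains(k);
  for (int i = 0; i < k; ++i) {
    chains[i].init(n1, n2, n3, tA.begin(), tB.begin(), tC.begin());
    chains[i].set_edges(as<IntegerMatrix>(edges_list[i]));
  }
  double w[3] = {weights[0], weights[1], weights[2]};
  std::vector<OpStats> stats(k);
  std::vector<long> swap_att(std::max(k - 1, 0), 0), swap_acc(std::max(k - 1, 0), 0);
  std::vector<IntegerMatrix> samples;
  std::vector<double> cold_trace, visits;
  if (track_states) {
    if (chains[0].N > 20) stop("state tracking only supported for up to 20 cells");
    visits.assign(1UL << chains[0].N, 0.0);
  }
  long long cold_steps = 0, cold_zero = 0, since_harvest = 0;
  long best_energy = chains[0].energy;
  long long steps = (long long)n_steps, t = 0;
  GetRNGstate();
  for (t = 1; t <= steps; ++t) {
    if (unif_rand() < 0.5) {
      int i = runif_int(k);
      chain_step(chains[i], temps[i], w, stats[i]);
      if (i == 0) {
        ++cold_steps; ++since_harvest;
        if (chains[0].energy < best_energy) best_energy = chains[0].energy;
        if (chains[0].energy == 0) ++cold_zero;
        if (cold_energy_every > 0 && cold_steps % cold_energy_every == 0)
          cold_trace.push_back((double)chains[0].energy);
        if (harvest && chains[0].energy == 0 && since_harvest >= spacing) {
          samples.push_back(chains[0].get_edges());
          since_harvest = 0;
          if (max_samples > 0 && (int)samples.size() >= max_samples) break;
        }
      }
    } else if (k > 1) {
      int i = runif_int(k - 1);
      ++swap_att[i];
      double lr = ((double)chains[i].energy - (double)chains[i + 1].energy) *
                  (1.0 / temps[i] - 1.0 / temps[i + 1]);
      if (lr >= 0 || log(unif_rand()) <= lr) {
        std::swap(chains[i], chains[i + 1]);
        if (i == 0) best_energy = std::min(best_energy, (long)chains[0].energy);
        ++swap_acc[i];
      }
    }
    if (track_states) visits[chains[0].mask] += 1.0;
    if ((t & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  PutRNGstate();
  List states(k), op_stats(k);
  NumericVector energies(k);
  for (int i = 0; i < k; ++i) {
    states[i] = chains[i].get_edges();
    op_stats[i] = stats_matrix(stats[i]);
    energies[i] = (double)chains[i].energy;
  }
  List smp(samples.size());
  for (size_t i = 0; i < samples.size(); ++i) smp[i] = samples[i];
  return List::create(
      _["states"] = states, _["energies"] = energies,
      _["samples"] = smp, _["op_stats"] = op_stats,
      _["swap_attempts"] = IntegerVector(swap_att.begin(), swap_att.end()),
      _["swap_accepts"] = IntegerVector(swap_acc.begin(), swap_acc.end()),
      _["cold_steps"] = (double)cold_steps,
      _["cold_zero_steps"] = (double)cold_zero,
      _["cold_energy_trace"] = NumericVector(cold_trace.begin(), cold_trace.end()),
      _["best_cold_energy"] = (double)best_energy,
      _["steps_done"] = (double)std::min(t, steps),
      _["state_visits"] = NumericVector(visits.begin(), visits.end()));
}
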