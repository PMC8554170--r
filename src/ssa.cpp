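// Gibson-Bruck next-reaction stochastic simulation core.
//
// Exact SSA over a concrete mass-action network: absolute tentative firing
// times live in an indexed binary min-heap; after each firing only the fired
// reaction redraws while dependent reactions have their times rescaled by
// the old/new propensity ratio. Ties are broken by reaction index. Clamped
// species participate in propensities but their counts never change
// (consumed copies are replenished). Uses R's RNG so that set.seed() in R
// makes trajectories exactly reproducible.

#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();

// indexed binary min-heap over (time, reaction index)
struct IndexedHeap {
  std::vector<int> heap;      // heap position -> reaction
  std::vector<int> pos;       // reaction -> heap position
  std::vector<double> key;    // reaction -> time

  explicit IndexedHeap(int n) : heap(n), pos(n), key(n, INF) {
    for (int i = 0; i < n; ++i) { heap[i] = i; pos[i] = i; }
  }
  bool less(int a, int b) const {
    if (key[a] != key[b]) return key[a] < key[b];
    return a < b;  // deterministic tie-break by reaction index
  }
  void swap_nodes(int i, int j) {
    std::swap(heap[i], heap[j]);
    pos[heap[i]] = i;
    pos[heap[j]] = j;
  }
  void up(int i) {
    while (i > 0) {
      int p = (i - 1) / 2;
      if (less(heap[i], heap[p])) { swap_nodes(i, p); i = p; }
      else break;
    }
  }
  void down(int i) {
    int n = (int)heap.size();
    for (;;) {
      int l = 2 * i + 1, r = 2 * i + 2, m = i;
      if (l < n && less(heap[l], heap[m])) m = l;
      if (r < n && less(heap[r], heap[m])) m = r;
      if (m == i) break;
      swap_nodes(i, m);
      i = m;
    }
  }
  void update(int rxn, double t) {
    double old = key[rxn];
    key[rxn] = t;
    if (t < old) up(pos[rxn]); else down(pos[rxn]);
  }
  int top() const { return heap[0]; }
  double top_key() const { return key[heap[0]]; }
};

inline double propensity(int order, int r1, int r2, double c,
                         const std::vector<double>& x) {
  if (order == 0) return c;
  if (order == 1) return c * x[r1];
  if (r1 == r2) return c * x[r1] * (x[r1] - 1.0) / 2.0;
  return c * x[r1] * x[r2];
}

} // namespace

// [[Rcpp::export(name = ".ssa_core")]]
List ssa_core(IntegerVector re1, IntegerVector re2, IntegerVector order,
              NumericVector cvec, List nd_idx, List nd_delta, List dep,
              IntegerVector pathway, NumericVector init,
              LogicalVector clamped, NumericVector grid,
              double t_end, double total_cap, double species_cap,
              double max_events) {
  const int R = re1.size();
  const int S = init.size();
  const int G = grid.size();
  const int NPATH = 6;

  std::vector<double> x(init.begin(), init.end());
  double total = 0.0;
  for (int s = 0; s < S; ++s) total += x[s];

  // flatten stoichiometry and dependencies
  std::vector<std::vector<int>> ndi(R), ndd(R), dg(R);
  for (int i = 0; i < R; ++i) {
    IntegerVector a = nd_idx[i], b = nd_delta[i], d = dep[i];
    ndi[i].assign(a.begin(), a.end());
    ndd[i].assign(b.begin(), b.end());
    dg[i].assign(d.begin(), d.end());
  }

  std::vector<double> a(R);
  IndexedHeap heap(R);
  RNGScope scope;
  for (int i = 0; i < R; ++i) {
    a[i] = propensity(order[i], re1[i] - 1, re2[i] - 1, cvec[i], x);
    if (a[i] < 0) stop("negative propensity for reaction %d", i + 1);
    heap.update(i, a[i] > 0 ? R::rexp(1.0) / a[i] : INF);
  }

  NumericMatrix counts(G, S);
  NumericMatrix tallies(G, NPATH);
  NumericVector rxn_count(R);
  std::vector<double> path_cum(NPATH, 0.0);

  double t = 0.0;
  int g = 0;
  double n_events = 0.0;
  int status = 0; // 0 completed, 1 count-cap, 2 max-events

  auto record_until = [&](double upto) {
    while (g < G && grid[g] <= upto) {
      for (int s = 0; s < S; ++s) counts(g, s) = x[s];
      for (int p = 0; p < NPATH; ++p) tallies(g, p) = path_cum[p];
      ++g;
    }
  };

  if (R == 0) {
    record_until(t_end);
    return List::create(_["counts"] = counts, _["tallies"] = tallies,
                        _["rxn_count"] = rxn_count, _["status"] = 0,
                        _["t_final"] = t_end, _["n_events"] = 0.0);
  }

  for (;;) {
    int mu = heap.top();
    double t_next = heap.top_key();
    if (t_next > t_end || !std::isfinite(t_next)) {
      t = t_end;
      record_until(t_end);
      break;
    }
    record_until(std::nextafter(t_next, 0.0)); // grid points strictly before event
    t = t_next;

    // fire mu
    const std::vector<int>& idx = ndi[mu];
    const std::vector<int>& del = ndd[mu];
    bool cap_hit = false;
    for (size_t k = 0; k < idx.size(); ++k) {
      int s = idx[k] - 1;
      if (clamped[s]) continue;  // replenished / held constant
      x[s] += del[k];
      total += del[k];
      if (x[s] < 0) stop("species count went negative (reaction %d)", mu + 1);
      if (x[s] > species_cap) cap_hit = true;
    }
    if (total > total_cap) cap_hit = true;
    rxn_count[mu] += 1.0;
    path_cum[pathway[mu] - 1] += 1.0;
    n_events += 1.0;

    // update fired reaction: fresh draw
    double a_new = propensity(order[mu], re1[mu] - 1, re2[mu] - 1, cvec[mu], x);
    a[mu] = a_new;
    heap.update(mu, a_new > 0 ? t + R::rexp(1.0) / a_new : INF);

    // dependents: rescale or redraw
    for (int j : dg[mu]) {
      int jj = j - 1;
      if (jj == mu) continue;
      double a_old = a[jj];
      double anew = propensity(order[jj], re1[jj] - 1, re2[jj] - 1, cvec[jj], x);
      if (anew == a_old) continue;
      a[jj] = anew;
      double tj = heap.key[jj];
      if (anew <= 0) {
        heap.update(jj, INF);
      } else if (a_old > 0 && std::isfinite(tj)) {
        heap.update(jj, t + (a_old / anew) * (tj - t));
      } else {
        heap.update(jj, t + R::rexp(1.0) / anew);
      }
    }

    if (cap_hit) { status = 1; record_until(t_end); break; }
    if (n_events >= max_events) { status = 2; record_until(t_end); break; }
  }

  return List::create(
    _["counts"] = counts,
    _["tallies"] = tallies,
    _["rxn_count"] = rxn_count,
    _["status"] = status,
    _["t_final"] = t,
    _["n_events"] = n_events);
}
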