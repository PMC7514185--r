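// Per-size clique counting by depth-bounded recursive expansion.  Every
// clique (not only maximal ones) is counted exactly once: vertices are
// visited in a fixed order and a clique is extended only by neighbours
// with a larger index than all current members.

#include <Rcpp.h>
#include <vector>
#include <cstdint>

using namespace Rcpp;

namespace {

struct CliqueCounter {
  int n;
  int k_max;
  std::int64_t budget;           // remaining node expansions
  const std::vector<std::vector<int>>& adj;  // sorted neighbour lists
  std::vector<double> counts;    // counts[k - 1] = number of k-cliques
  bool exhausted = false;

  CliqueCounter(int n_, int k_max_, std::int64_t budget_,
                const std::vector<std::vector<int>>& adj_)
      : n(n_), k_max(k_max_), budget(budget_), adj(adj_),
        counts(k_max_, 0.0) {}

  // cand: vertices > all clique members adjacent to every member
  void expand(int depth, const std::vector<int>& cand) {
    for (std::size_t c = 0; c < cand.size(); ++c) {
      if (--budget < 0) { exhausted = true; return; }
      int v = cand[c];
      counts[depth - 1] += 1.0;
      if (depth == k_max) continue;
      std::vector<int> next;
      // intersect cand[c+1 ..] with neighbours of v (both sorted ascending)
      std::size_t a = c + 1;
      const std::vector<int>& nb = adj[v];
      std::size_t b = 0;
      while (a < cand.size() && b < nb.size()) {
        if (cand[a] < nb[b]) ++a;
        else if (nb[b] < cand[a]) ++b;
        else { next.push_back(cand[a]); ++a; ++b; }
      }
      if (!next.empty()) expand(depth + 1, next);
      if (exhausted) return;
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".cpp_count_cliques")]]
List cpp_count_cliques(int n, IntegerVector edge_a, IntegerVector edge_b,
                       int k_max, double budget) {
  std::vector<std::vector<int>> adj(n);
  for (int e = 0; e < edge_a.size(); ++e) {
    int a = edge_a[e] - 1, b = edge_b[e] - 1;
    adj[a].push_back(b);
    adj[b].push_back(a);
  }
  for (int i = 0; i < n; ++i) {
    std::sort(adj[i].begin(), adj[i].end());
    adj[i].erase(std::unique(adj[i].begin(), adj[i].end()), adj[i].end());
  }
  CliqueCounter cc(n, k_max, static_cast<std::int64_t>(budget), adj);
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;
  cc.expand(1, all);
  return List::create(_["counts"] = NumericVector(cc.counts.begin(),
                                                  cc.counts.end()),
                      _["exhausted"] = cc.exhausted);
}
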