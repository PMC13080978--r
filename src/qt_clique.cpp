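#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Quality-Threshold clustering on a precomputed distance matrix.
//
// A cluster with diameter (max pairwise distance) <= t is exactly a clique
// in the graph whose edges join items at distance <= t. Each round commits
// the maximum clique among the remaining items, found exactly: connected
// components are located first; a complete component is its own maximum
// clique (the common case for well-separated data), otherwise a
// deterministic branch-and-bound with a greedy-coloring bound is run.
// Ties between equally sized maxima resolve to the first found in a fixed
// ascending-index search order, so the output is fully deterministic.

static void expand(const std::vector<std::vector<char>>& adj,
                   std::vector<int>& R,
                   std::vector<int>& P,
                   std::vector<int>& best) {
  if (P.empty()) {
    if (R.size() > best.size()) best = R;
    return;
  }
  // greedy coloring bound on P (P is kept sorted ascending)
  size_t n = P.size();
  std::vector<int> color(n, 0);
  int maxc = 0;
  for (size_t i = 0; i < n; ++i) {
    int c = 1;
    for (;; ++c) {
      bool clash = false;
      for (size_t j = 0; j < i; ++j) {
        if (color[j] == c && adj[P[i]][P[j]]) { clash = true; break; }
      }
      if (!clash) break;
    }
    color[i] = c;
    if (c > maxc) maxc = c;
  }
  if (R.size() + (size_t)maxc <= best.size()) return;  // bound
  for (size_t i = 0; i < n; ++i) {
    if (R.size() + (n - i) <= best.size()) return;
    int v = P[i];
    R.push_back(v);
    std::vector<int> P2;
    for (size_t j = i + 1; j < n; ++j) {
      if (adj[v][P[j]]) P2.push_back(P[j]);
    }
    expand(adj, R, P2, best);
    R.pop_back();
  }
}

// [[Rcpp::export]]
IntegerVector qt_cluster_cpp(NumericMatrix D, double threshold) {
  int n = D.nrow();
  std::vector<std::vector<char>> adj(n, std::vector<char>(n, 0));
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      adj[i][j] = (i != j && D(i, j) <= threshold) ? 1 : 0;
    }
  }
  IntegerVector labels(n, NA_INTEGER);
  std::vector<char> active(n, 1);
  int next_label = 1;
  int remaining = n;
  while (remaining > 0) {
    // connected components of the active subgraph
    std::vector<int> comp(n, -1);
    int ncomp = 0;
    for (int s = 0; s < n; ++s) {
      if (!active[s] || comp[s] >= 0) continue;
      std::vector<int> stack{s};
      comp[s] = ncomp;
      while (!stack.empty()) {
        int v = stack.back(); stack.pop_back();
        for (int u = 0; u < n; ++u) {
          if (active[u] && comp[u] < 0 && adj[v][u]) {
            comp[u] = ncomp;
            stack.push_back(u);
          }
        }
      }
      ++ncomp;
    }
    std::vector<int> best;
    for (int c = 0; c < ncomp; ++c) {
      std::vector<int> members;
      for (int v = 0; v < n; ++v) {
        if (active[v] && comp[v] == c) members.push_back(v);
      }
      if (members.size() <= best.size()) continue;  // cannot beat best
      // complete-component fast path
      bool complete = true;
      for (size_t i = 0; i + 1 < members.size() && complete; ++i) {
        for (size_t j = i + 1; j < members.size(); ++j) {
          if (!adj[members[i]][members[j]]) { complete = false; break; }
        }
      }
      std::vector<int> cand;
      if (complete) {
        cand = members;
      } else {
        std::vector<int> R;
        cand = best;  // lower bound carried over for pruning
        expand(adj, R, members, cand);
      }
      if (cand.size() > best.size()) best = cand;
    }
    for (int v : best) {
      labels[v] = next_label;
      active[v] = 0;
    }
    remaining -= (int)best.size();
    ++next_label;
  }
  return labels;
}
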