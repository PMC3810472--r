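#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Maslov-Sneppen double-edge swaps on an edge list (1-based node indices,
// each undirected edge once). Uses R's RNG so results follow set.seed().
// Attempts stop after 100 * n_swaps tries if too few swaps succeed.
// [[Rcpp::export]]
List rewire_cpp(IntegerMatrix edges, int n_nodes, int n_swaps) {
  int m = edges.nrow();
  std::vector<int> a(m), b(m);
  // dense adjacency bitmap, 0-based
  std::vector<unsigned char> adj((size_t)n_nodes * n_nodes, 0);
  auto at = [&](int i, int j) -> unsigned char& {
    return adj[(size_t)(i - 1) * n_nodes + (j - 1)];
  };
  for (int e = 0; e < m; ++e) {
    a[e] = edges(e, 0);
    b[e] = edges(e, 1);
    at(a[e], b[e]) = at(b[e], a[e]) = 1;
  }
  RNGScope scope;
  long long max_attempts = 100LL * (n_swaps > 0 ? n_swaps : 1);
  int success = 0;
  for (long long att = 0; att < max_attempts && success < n_swaps; ++att) {
    int e1 = (int)(unif_rand() * m);
    int e2 = (int)(unif_rand() * m);
    if (e1 == e2) continue;
    int x1 = a[e1], y1 = b[e1], x2 = a[e2], y2 = b[e2];
    if (unif_rand() < 0.5) std::swap(x2, y2);
    // proposed new edges: (x1, y2) and (x2, y1)
    if (x1 == y2 || x2 == y1) continue;                 // self-loop
    if (x1 == x2 || y1 == y2) continue;                 // no-op swap
    if (at(x1, y2) || at(x2, y1)) continue;             // multi-edge
    at(x1, y1) = at(y1, x1) = 0;
    at(x2, y2) = at(y2, x2) = 0;
    at(x1, y2) = at(y2, x1) = 1;
    at(x2, y1) = at(y1, x2) = 1;
    a[e1] = std::min(x1, y2); b[e1] = std::max(x1, y2);
    a[e2] = std::min(x2, y1); b[e2] = std::max(x2, y1);
    ++success;
  }
  IntegerMatrix out(m, 2);
  for (int e = 0; e < m; ++e) { out(e, 0) = a[e]; out(e, 1) = b[e]; }
  return List::create(_["edges"] = out, _["n_success"] = success);
}

// All-pairs hop-count distances by breadth-first search on a binary
// adjacency matrix; -1 marks unreachable pairs.
// [[Rcpp::export]]
IntegerMatrix bfs_distances_cpp(LogicalMatrix adj) {
  int n = adj.nrow();
  std::vector<std::vector<int>> nb(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (adj(i, j)) nb[i].push_back(j);
  IntegerMatrix d(n, n);
  std::fill(d.begin(), d.end(), -1);
  std::vector<int> queue(n);
  for (int s = 0; s < n; ++s) {
    d(s, s) = 0;
    int head = 0, tail = 0;
    queue[tail++] = s;
    while (head < tail) {
      int u = queue[head++];
      int du = d(s, u);
      for (int v : nb[u]) {
        if (d(s, v) < 0) {
          d(s, v) = du + 1;
          queue[tail++] = v;
        }
      }
    }
  }
  return d;
}
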