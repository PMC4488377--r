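#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Weighted directed betweenness centrality (Brandes accumulation) on a
// dense distance matrix. d(i,j) is the edge length from i to j; R_PosInf
// encodes an absent edge. All co-minimal shortest paths are counted; two
// path lengths are considered tied when they agree within a relative
// tolerance of 1e-12. Dijkstra with O(N^2) selection: the matrices here
// are small (tens of nodes) but evaluated up to 1e5 times in the
// randomization nulls.
// [[Rcpp::export(name = ".brandes_betweenness")]]
NumericVector brandes_betweenness(NumericMatrix d) {
  const int n = d.nrow();
  const double inf = std::numeric_limits<double>::infinity();
  const double rel_tol = 1e-12;
  NumericVector bc(n);
  if (n < 3) return bc;

  std::vector<double> dist(n);
  std::vector<double> sigma(n), delta(n);
  std::vector<bool> done(n);
  std::vector<int> order_visited(n);
  // predecessor lists as flat adjacency (n x n is tiny)
  std::vector<std::vector<int>> pred(n);

  for (int s = 0; s < n; ++s) {
    for (int v = 0; v < n; ++v) {
      dist[v] = inf; sigma[v] = 0.0; delta[v] = 0.0; done[v] = false;
      pred[v].clear();
    }
    dist[s] = 0.0; sigma[s] = 1.0;
    int n_visited = 0;

    for (int iter = 0; iter < n; ++iter) {
      // extract-min among unsettled nodes
      int u = -1; double best = inf;
      for (int v = 0; v < n; ++v)
        if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
      if (u < 0) break;  // remaining nodes unreachable
      done[u] = true;
      order_visited[n_visited++] = u;
      // relax outgoing edges u -> w
      for (int w = 0; w < n; ++w) {
        if (w == u || done[w]) continue;
        double len = d(u, w);
        if (len == inf) continue;
        double alt = dist[u] + len;
        if (dist[w] == inf) {
          dist[w] = alt;
          sigma[w] = sigma[u];
          pred[w].assign(1, u);
        } else {
          double tol = rel_tol * std::max(1.0, std::max(std::abs(alt),
                                                        std::abs(dist[w])));
          if (alt < dist[w] - tol) {
            dist[w] = alt;
            sigma[w] = sigma[u];
            pred[w].assign(1, u);
          } else if (std::abs(alt - dist[w]) <= tol) {
            sigma[w] += sigma[u];
            pred[w].push_back(u);
          }
        }
      }
    }

    // accumulate dependencies in reverse visit order
    for (int i = n_visited - 1; i >= 1; --i) {
      int w = order_visited[i];
      for (int u : pred[w])
        delta[u] += sigma[u] / sigma[w] * (1.0 + delta[w]);
      bc[w] += delta[w];
    }
  }
  return bc;
}

// Betweenness of each of `n_rand` draws in which the off-diagonal weight
// multiset is permuted uniformly over the ordered pairs; weights are
// transformed to distances (w > 0 -> 1/w, else Inf). `perm` is an
// (n_rand x E) 1-based matrix of permutation indices drawn in R so that
// all randomness flows through R's RNG.
// [[Rcpp::export(name = ".null_betweenness_weighted")]]
NumericMatrix null_betweenness_weighted(NumericVector w_off,
                                        IntegerMatrix perm, int n_nodes) {
  const int n_rand = perm.nrow();
  const int E = w_off.size();
  NumericMatrix out(n_rand, n_nodes);
  NumericMatrix d(n_nodes, n_nodes);
  std::vector<int> off_rows, off_cols;
  off_rows.reserve(E); off_cols.reserve(E);
  for (int j = 0; j < n_nodes; ++j)
    for (int i = 0; i < n_nodes; ++i)
      if (i != j) { off_rows.push_back(i); off_cols.push_back(j); }
  for (int r = 0; r < n_rand; ++r) {
    for (int e = 0; e < E; ++e) {
      double w = w_off[perm(r, e) - 1];
      d(off_rows[e], off_cols[e]) = (w > 0) ? 1.0 / w : R_PosInf;
    }
    out(r, _) = brandes_betweenness(d);
  }
  return out;
}

// Betweenness and degree of each of `n_rand` binary draws placing E edges
// uniformly among the ordered pairs. `slots` is an (n_rand x E) 1-based
// matrix of sampled off-diagonal slot indices (column-major over the
// off-diagonal cells). Returns cbind(bc, outdegree, indegree) blocks.
// [[Rcpp::export(name = ".null_betweenness_binary")]]
List null_betweenness_binary(IntegerMatrix slots, int n_nodes) {
  const int n_rand = slots.nrow();
  const int E = slots.ncol();
  NumericMatrix bc(n_rand, n_nodes);
  IntegerMatrix outdeg(n_rand, n_nodes), indeg(n_rand, n_nodes);
  std::vector<int> off_rows, off_cols;
  for (int j = 0; j < n_nodes; ++j)
    for (int i = 0; i < n_nodes; ++i)
      if (i != j) { off_rows.push_back(i); off_cols.push_back(j); }
  NumericMatrix d(n_nodes, n_nodes);
  for (int r = 0; r < n_rand; ++r) {
    std::fill(d.begin(), d.end(), R_PosInf);
    for (int v = 0; v < n_nodes; ++v) d(v, v) = 0.0;
    for (int e = 0; e < E; ++e) {
      int k = slots(r, e) - 1;
      int i = off_rows[k], j = off_cols[k];
      d(i, j) = 1.0;
      outdeg(r, i) += 1;
      indeg(r, j) += 1;
    }
    bc(r, _) = brandes_betweenness(d);
  }
  return List::create(_["betweenness"] = bc, _["outdegree"] = outdeg,
                      _["indegree"] = indeg);
}
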