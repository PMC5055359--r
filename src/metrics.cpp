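#include <Rcpp.h>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Floyd-Warshall all-pairs shortest paths over a dense symmetric length
// matrix (Inf = no edge, 0 diagonal). Sizes here are at most a few thousand
// nodes, where the dense cubic sweep is both simple and fast.
// [[Rcpp::export]]
NumericMatrix cpp_apsp(NumericMatrix W) {
  int n = W.nrow();
  NumericMatrix D(clone(W));
  for (int k = 0; k < n; ++k) {
    for (int i = 0; i < n; ++i) {
      double dik = D(i, k);
      if (!R_finite(dik)) continue;
      for (int j = 0; j < n; ++j) {
        double alt = dik + D(k, j);
        if (alt < D(i, j)) D(i, j) = alt;
      }
    }
  }
  return D;
}

static double subgraph_efficiency(const NumericMatrix &W,
                                  const std::vector<int> &nb) {
  int m = (int)nb.size();
  if (m < 2) return 0.0;
  NumericMatrix S(m, m);
  for (int a = 0; a < m; ++a)
    for (int b = 0; b < m; ++b)
      S(a, b) = (a == b) ? 0.0 : W(nb[a], nb[b]);
  NumericMatrix D = cpp_apsp(S);
  double s = 0.0;
  for (int a = 0; a < m; ++a)
    for (int b = 0; b < m; ++b)
      if (a != b && R_finite(D(a, b)) && D(a, b) > 0.0) s += 1.0 / D(a, b);
  return s / ((double)m * (m - 1));
}

// Local efficiency per node: global efficiency of the subgraph induced by
// the node's neighbours, with paths restricted to that subgraph.
// [[Rcpp::export]]
NumericVector cpp_local_efficiency(NumericMatrix W) {
  int n = W.nrow();
  NumericVector le(n);
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    for (int j = 0; j < n; ++j)
      if (j != i && R_finite(W(i, j))) nb.push_back(j);
    le[i] = subgraph_efficiency(W, nb);
  }
  return le;
}

// Brandes betweenness with fractional counting over equal-length shortest
// paths; weighted Dijkstra (O(n^2) extraction, fine at these sizes).
// Returns raw (unnormalised) betweenness for an undirected graph.
// [[Rcpp::export]]
NumericVector cpp_betweenness(int n, IntegerVector from, IntegerVector to,
                              NumericVector len) {
  std::vector<std::vector<std::pair<int, double> > > adj(n);
  for (int e = 0; e < from.size(); ++e) {
    adj[from[e]].push_back(std::make_pair(to[e], len[e]));
    adj[to[e]].push_back(std::make_pair(from[e], len[e]));
  }
  NumericVector bc(n);
  std::vector<double> dist(n), sigma(n), delta(n);
  std::vector<bool> done(n);
  std::vector<std::vector<int> > pred(n);
  std::vector<int> order;
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(delta.begin(), delta.end(), 0.0);
    std::fill(done.begin(), done.end(), false);
    for (int i = 0; i < n; ++i) pred[i].clear();
    order.clear();
    dist[s] = 0.0;
    sigma[s] = 1.0;
    for (int it = 0; it < n; ++it) {
      int u = -1;
      double best = R_PosInf;
      for (int v = 0; v < n; ++v)
        if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
      if (u < 0) break;
      done[u] = true;
      order.push_back(u);
      for (size_t a = 0; a < adj[u].size(); ++a) {
        int v = adj[u][a].first;
        if (done[v]) continue;
        double alt = dist[u] + adj[u][a].second;
        if (alt < dist[v]) {
          dist[v] = alt;
          sigma[v] = sigma[u];
          pred[v].assign(1, u);
        } else if (alt == dist[v]) {
          sigma[v] += sigma[u];
          pred[v].push_back(u);
        }
      }
    }
    for (int k = (int)order.size() - 1; k >= 0; --k) {
      int w = order[k];
      for (size_t a = 0; a < pred[w].size(); ++a) {
        int u = pred[w][a];
        delta[u] += sigma[u] / sigma[w] * (1.0 + delta[w]);
      }
      if (w != s) bc[w] += delta[w];
    }
  }
  for (int i = 0; i < n; ++i) bc[i] /= 2.0;  // each pair counted twice
  return bc;
}

// Degree-preserving double-edge swaps. Two distinct edges (a,b), (c,d) are
// rewired to (a,d), (c,b); attempts creating self-loops or multi-edges are
// rejected. With lattice = true a swap is additionally accepted only when it
// does not increase the adjacency-band cost sum(|pos[i] - pos[j]|) under the
// supplied node ordering, driving the graph towards a banded (lattice-like)
// adjacency structure. Uses R's RNG, so results are reproducible under
// set.seed(). Returns the new edge matrix and the number of accepted swaps.
// [[Rcpp::export]]
List cpp_edge_swap(int n, IntegerMatrix edges, int nattempt, bool lattice,
                   IntegerVector pos) {
  int m = edges.nrow();
  std::vector<int> ef(m), et(m);
  std::unordered_set<long long> have;
  long long N = (long long)n + 1;
  for (int e = 0; e < m; ++e) {
    ef[e] = edges(e, 0);
    et[e] = edges(e, 1);
    int a = std::min(ef[e], et[e]), b = std::max(ef[e], et[e]);
    have.insert((long long)a * N + b);
  }
  int accepted = 0;
  for (int t = 0; t < nattempt; ++t) {
    int e1 = (int)(unif_rand() * m);
    int e2 = (int)(unif_rand() * m);
    if (e1 >= m) e1 = m - 1;
    if (e2 >= m) e2 = m - 1;
    if (e1 == e2) continue;
    int a = ef[e1], b = et[e1], c = ef[e2], d = et[e2];
    if (unif_rand() < 0.5) std::swap(c, d);
    // proposed edges (a,d) and (c,b)
    if (a == d || c == b) continue;
    if (a == c && b == d) continue;
    long long k_ad = (long long)std::min(a, d) * N + std::max(a, d);
    long long k_cb = (long long)std::min(c, b) * N + std::max(c, b);
    if (k_ad == k_cb) continue;
    if (have.count(k_ad) || have.count(k_cb)) continue;
    if (lattice) {
      double oldc = std::abs((double)pos[a - 1] - pos[b - 1]) +
                    std::abs((double)pos[c - 1] - pos[d - 1]);
      double newc = std::abs((double)pos[a - 1] - pos[d - 1]) +
                    std::abs((double)pos[c - 1] - pos[b - 1]);
      if (newc > oldc) continue;
    }
    long long k_ab = (long long)std::min(a, b) * N + std::max(a, b);
    long long k_cd = (long long)std::min(c, d) * N + std::max(c, d);
    have.erase(k_ab);
    have.erase(k_cd);
    have.insert(k_ad);
    have.insert(k_cb);
    ef[e1] = a; et[e1] = d;
    ef[e2] = c; et[e2] = b;
    ++accepted;
  }
  IntegerMatrix out(m, 2);
  for (int e = 0; e < m; ++e) {
    out(e, 0) = ef[e];
    out(e, 1) = et[e];
  }
  return List::create(Named("edges") = out, Named("accepted") = accepted);
}

// All-pairs hop-count distances by BFS from every source; much faster than
// the dense Floyd-Warshall when all edges count 1.
// [[Rcpp::export]]
NumericMatrix cpp_bfs_apsp(int n, IntegerVector from, IntegerVector to) {
  std::vector<std::vector<int> > adj(n);
  for (int e = 0; e < from.size(); ++e) {
    adj[from[e]].push_back(to[e]);
    adj[to[e]].push_back(from[e]);
  }
  NumericMatrix D(n, n);
  std::fill(D.begin(), D.end(), R_PosInf);
  std::vector<int> queue(n);
  for (int s = 0; s < n; ++s) {
    D(s, s) = 0.0;
    int head = 0, tail = 0;
    queue[tail++] = s;
    while (head < tail) {
      int u = queue[head++];
      double du = D(s, u);
      for (size_t a = 0; a < adj[u].size(); ++a) {
        int v = adj[u][a];
        if (!R_finite(D(s, v))) {
          D(s, v) = du + 1.0;
          queue[tail++] = v;
        }
      }
    }
  }
  return D;
}
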