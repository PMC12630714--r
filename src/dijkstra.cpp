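#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>

using namespace Rcpp;

// Single-source shortest paths with a deterministic tie rule: among
// equal-cost paths the lexicographically smallest node-index sequence is
// kept.  Node indices are expected to follow the sort order of node ids, so
// index order == lexicographic id order.  Edge weights must be > 0.

struct CSR {
  std::vector<int> head;      // size n+1
  std::vector<int> nbr;       // neighbour node index
  std::vector<double> w;      // edge weight
};

static CSR build_csr(int n, const IntegerVector &from, const IntegerVector &to,
                     const NumericVector &wt) {
  CSR g;
  int m = from.size();
  std::vector<int> deg(n, 0);
  for (int e = 0; e < m; ++e) { deg[from[e]]++; deg[to[e]]++; }
  g.head.assign(n + 1, 0);
  for (int i = 0; i < n; ++i) g.head[i + 1] = g.head[i] + deg[i];
  g.nbr.assign(2 * m, 0);
  g.w.assign(2 * m, 0.0);
  std::vector<int> pos(g.head.begin(), g.head.end() - 1);
  for (int e = 0; e < m; ++e) {
    g.nbr[pos[from[e]]] = to[e];  g.w[pos[from[e]]++] = wt[e];
    g.nbr[pos[to[e]]]   = from[e]; g.w[pos[to[e]]++]   = wt[e];
  }
  return g;
}

static std::vector<int> unwind(int v, const std::vector<int> &pred) {
  std::vector<int> path;
  for (int u = v; u != -1; u = pred[u]) path.push_back(u);
  std::reverse(path.begin(), path.end());
  return path;
}

// true if path(source..u) + [v] is lexicographically smaller than the
// currently stored path(source..v)
static bool lex_better(int u, int v, const std::vector<int> &pred) {
  std::vector<int> cand = unwind(u, pred);
  cand.push_back(v);
  std::vector<int> cur = unwind(v, pred);
  return std::lexicographical_compare(cand.begin(), cand.end(),
                                      cur.begin(), cur.end());
}

static void dijkstra(const CSR &g, int n, int source,
                     std::vector<double> &dist, std::vector<int> &pred) {
  const double INF = std::numeric_limits<double>::infinity();
  dist.assign(n, INF);
  pred.assign(n, -1);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  dist[source] = 0.0;
  pq.push(QE(0.0, source));
  std::vector<char> done(n, 0);
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    int u = top.second;
    if (done[u]) continue;
    done[u] = 1;
    for (int k = g.head[u]; k < g.head[u + 1]; ++k) {
      int v = g.nbr[k];
      double nd = dist[u] + g.w[k];
      if (nd < dist[v]) {
        dist[v] = nd; pred[v] = u;
        pq.push(QE(nd, v));
      } else if (nd == dist[v] && pred[v] != -1 && lex_better(u, v, pred)) {
        pred[v] = u;  // same cost, lexicographically smaller route
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_dijkstra")]]
List cpp_dijkstra(int n, IntegerVector from, IntegerVector to,
                  NumericVector weight, int source) {
  CSR g = build_csr(n, from, to, weight);
  std::vector<double> dist; std::vector<int> pred;
  dijkstra(g, n, source, dist, pred);
  return List::create(_["dist"] = NumericVector(dist.begin(), dist.end()),
                      _["pred"] = IntegerVector(pred.begin(), pred.end()));
}

// Gravity-flow centrality: for every unordered pair of distinct cities,
// route the flow P_o*P_d / T^gamma along the fastest path and accumulate it
// on the cities the route passes through.  `city_node` maps city k to its
// node index; `pop` is aligned with it.  Unreachable pairs contribute 0 and
// are counted.
// [[Rcpp::export(name = ".cpp_centrality")]]
List cpp_centrality(int n, IntegerVector from, IntegerVector to,
                    NumericVector weight, IntegerVector city_node,
                    NumericVector pop, double gamma, bool include_endpoints) {
  CSR g = build_csr(n, from, to, weight);
  int nc = city_node.size();
  std::vector<int> node_city(n, -1);
  for (int k = 0; k < nc; ++k) node_city[city_node[k]] = k;
  NumericVector cent(nc, 0.0);
  int unreachable = 0;
  std::vector<double> dist; std::vector<int> pred;
  for (int o = 0; o < nc; ++o) {
    dijkstra(g, n, city_node[o], dist, pred);
    for (int d = o + 1; d < nc; ++d) {
      double t = dist[city_node[d]];
      if (!std::isfinite(t)) { unreachable++; continue; }
      double flow = pop[o] * pop[d] / std::pow(t, gamma);
      if (include_endpoints) { cent[o] += flow; cent[d] += flow; }
      // walk predecessor chain; endpoints are city_node[d] and city_node[o]
      for (int u = pred[city_node[d]]; u != -1 && u != city_node[o];
           u = pred[u]) {
        int k = node_city[u];
        if (k >= 0) cent[k] += flow;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["centrality"] = cent,
                      _["n_unreachable_pairs"] = unreachable);
}

// Nearest city for each query point by haversine distance (km), with ties
// broken in favour of the smallest city index (pass cities sorted by id).
// Returns 1-based indices and the distance to the nearest city.  The
// arithmetic mirrors the R-level haversine_km() operation for operation so
// both routes agree bitwise (the assignment threshold is a strict
// inequality, so the two distance paths must not disagree by an ulp).
// [[Rcpp::export(name = ".cpp_nearest_city")]]
List cpp_nearest_city(NumericVector qlon, NumericVector qlat,
                      NumericVector clon, NumericVector clat) {
  const double to_rad = M_PI / 180.0;
  int nq = qlon.size(), nc = clon.size();
  std::vector<double> ccos(nc);
  for (int j = 0; j < nc; ++j) ccos[j] = std::cos(clat[j] * to_rad);
  IntegerVector best(nq);
  NumericVector dist(nq);
  for (int i = 0; i < nq; ++i) {
    double cphi_i = std::cos(qlat[i] * to_rad);
    double besta = std::numeric_limits<double>::infinity();
    int bestj = 0;
    for (int j = 0; j < nc; ++j) {
      double dlat = (clat[j] - qlat[i]) * to_rad;
      double dlon = (clon[j] - qlon[i]) * to_rad;
      double sdlat = std::sin(dlat / 2.0);
      double sdlon = std::sin(dlon / 2.0);
      double a = sdlat * sdlat + (cphi_i * ccos[j]) * (sdlon * sdlon);
      if (a < besta) { besta = a; bestj = j; }
    }
    best[i] = bestj + 1;
    double s = std::sqrt(besta);
    if (s > 1.0) s = 1.0;
    dist[i] = 2.0 * 6371.0 * std::asin(s);
  }
  return List::create(_["index"] = best, _["distance_km"] = dist);
}
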