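#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>

using namespace Rcpp;

// Min-cost integer flow with free flow value, by successive shortest
// paths with node potentials. Negative arc costs are the normal case
// here (unmatched-read penalties and below-target coverage enter as
// negative difference costs), so initial potentials come from a
// Bellman-Ford pass; the input edge list is topologically ordered
// (s, C^X, X, Y, C^Y, t), so few passes are needed. Augmentation stops
// when the cheapest augmenting path has nonnegative cost: at that point
// no larger or smaller flow value can cost less (path costs are
// non-decreasing over successive shortest-path augmentations).
//
// Nodes are 1-based as passed from R. Capacity INT_MAX/2 plays infinity.

static const double DINF = std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List mcf_free_flow(int n, int s, int t,
                   IntegerVector from, IntegerVector to,
                   IntegerVector cap, NumericVector cost) {
  const int m = from.size();
  std::vector<int>    eto;   eto.reserve(2 * m);
  std::vector<int>    ecap;  ecap.reserve(2 * m);
  std::vector<double> ecost; ecost.reserve(2 * m);
  std::vector<std::vector<int> > adj(n + 1);
  for (int i = 0; i < m; ++i) {
    int u = from[i], v = to[i];
    if (u < 1 || u > n || v < 1 || v > n) stop("edge endpoint out of range");
    adj[u].push_back(eto.size());
    eto.push_back(v); ecap.push_back(cap[i]); ecost.push_back(cost[i]);
    adj[v].push_back(eto.size());
    eto.push_back(u); ecap.push_back(0);      ecost.push_back(-cost[i]);
  }

  std::vector<double> pot(n + 1, DINF);
  pot[s] = 0.0;
  // Bellman-Ford over residual arcs with positive capacity
  for (int pass = 0; pass <= n; ++pass) {
    bool changed = false;
    for (int e = 0; e < (int)eto.size(); ++e) {
      if (ecap[e] <= 0) continue;
      int u = (e % 2 == 0) ? from[e / 2] : to[e / 2];
      if (pot[u] == DINF) continue;
      double nd = pot[u] + ecost[e];
      if (nd < pot[eto[e]] - 1e-12) { pot[eto[e]] = nd; changed = true; }
    }
    if (!changed) break;
    if (pass == n) stop("negative cycle in flow network");
  }

  std::vector<double> dist(n + 1);
  std::vector<int> pedge(n + 1);
  double total_cost = 0.0;
  long long total_value = 0;

  typedef std::pair<double, int> QE;
  while (true) {
    std::fill(dist.begin(), dist.end(), DINF);
    std::fill(pedge.begin(), pedge.end(), -1);
    dist[s] = 0.0;
    std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
    pq.push(QE(0.0, s));
    while (!pq.empty()) {
      QE top = pq.top(); pq.pop();
      int u = top.second;
      if (top.first > dist[u] + 1e-12) continue;
      if (u == t) break;  // sink settled: shortest s-t distance final
      for (size_t k = 0; k < adj[u].size(); ++k) {
        int e = adj[u][k];
        if (ecap[e] <= 0) continue;
        int v = eto[e];
        if (pot[v] == DINF) continue;  // never reachable from s
        double rc = ecost[e] + pot[u] - pot[v];
        if (rc < -1e-9) stop("internal: negative reduced cost");
        if (rc < 0) rc = 0;
        double nd = dist[u] + rc;
        if (nd < dist[v] - 1e-12) {
          dist[v] = nd; pedge[v] = e;
          pq.push(QE(nd, v));
        }
      }
    }
    if (dist[t] == DINF) break;
    double path_cost = dist[t] + pot[t] - pot[s];
    if (path_cost >= -1e-12) break;
    // bottleneck
    int bneck = std::numeric_limits<int>::max();
    for (int v = t; v != s; ) {
      int e = pedge[v];
      if (ecap[e] < bneck) bneck = ecap[e];
      v = (e % 2 == 0) ? from[e / 2] : to[e / 2];
    }
    for (int v = t; v != s; ) {
      int e = pedge[v];
      ecap[e] -= bneck;
      ecap[e ^ 1] += bneck;
      v = (e % 2 == 0) ? from[e / 2] : to[e / 2];
    }
    total_cost += (double)bneck * path_cost;
    total_value += bneck;
    // unsettled nodes get dist[t] so reduced costs stay nonnegative
    for (int v = 1; v <= n; ++v) {
      if (pot[v] == DINF) continue;
      pot[v] += (dist[v] < dist[t]) ? dist[v] : dist[t];
    }
  }

  IntegerVector flow(m);
  for (int i = 0; i < m; ++i) flow[i] = cap[i] - ecap[2 * i];
  return List::create(_["flow"] = flow,
                      _["value"] = (double)total_value,
                      _["cost"] = total_cost);
}
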