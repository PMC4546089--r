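// Two-phase Louvain modularity optimization on a weighted undirected graph.
// Deterministic multistart: node visit order is shuffled per restart from the
// seed, the best-Q partition over restarts is kept (first winner on ties).

#include <Rcpp.h>
#include <algorithm>
#include <map>
#include <random>
#include <cstdint>
using namespace Rcpp;

struct Graph {
  int n;
  std::vector<std::vector<std::pair<int, double> > > adj; // neighbor, weight
  std::vector<double> selfw;                              // self-loop weight
  double m;                                               // total edge weight
};

// Q = sum_c [ intra_c / m - (Stot_c / (2m))^2 ], intra counts each
// undirected edge once and each self-loop once; Stot sums weighted degrees
// (a self-loop contributes 2w to its node's degree).
static double modularity_of(const Graph &g, const std::vector<int> &comm) {
  int nc = 0;
  for (int i = 0; i < g.n; ++i) nc = std::max(nc, comm[i] + 1);
  std::vector<double> intra(nc, 0.0), stot(nc, 0.0);
  for (int i = 0; i < g.n; ++i) {
    double deg = 2.0 * g.selfw[i];
    for (size_t t = 0; t < g.adj[i].size(); ++t) {
      deg += g.adj[i][t].second;
      int j = g.adj[i][t].first;
      if (j > i && comm[j] == comm[i]) intra[comm[i]] += g.adj[i][t].second;
    }
    intra[comm[i]] += g.selfw[i];
    stot[comm[i]] += deg;
  }
  double q = 0.0, m2 = 2.0 * g.m;
  for (int c = 0; c < nc; ++c)
    q += intra[c] / g.m - (stot[c] / m2) * (stot[c] / m2);
  return q;
}

// One level of local moving; returns true if any node moved.
static bool one_level(const Graph &g, std::vector<int> &comm,
                      std::mt19937 &rng) {
  const int n = g.n;
  std::vector<double> k(n, 0.0);
  for (int i = 0; i < n; ++i) {
    k[i] = 2.0 * g.selfw[i];
    for (size_t t = 0; t < g.adj[i].size(); ++t) k[i] += g.adj[i][t].second;
  }
  std::vector<double> stot(n, 0.0);
  for (int i = 0; i < n; ++i) stot[comm[i]] += k[i];
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::shuffle(order.begin(), order.end(), rng);
  const double m2 = 2.0 * g.m;
  bool any_move = false;
  std::vector<double> wcomm(n, 0.0); // weight from node to community
  std::vector<int> touched;
  bool improved = true;
  while (improved) {
    improved = false;
    for (int t0 = 0; t0 < n; ++t0) {
      int i = order[t0];
      int old_c = comm[i];
      touched.clear();
      for (size_t t = 0; t < g.adj[i].size(); ++t) {
        int c = comm[g.adj[i][t].first];
        if (wcomm[c] == 0.0) touched.push_back(c);
        wcomm[c] += g.adj[i][t].second;
      }
      if (wcomm[old_c] == 0.0) touched.push_back(old_c); // allow staying
      stot[old_c] -= k[i];
      // gain(c) = w_{i,c} - stot_c * k_i / (2m); tie -> lower community id
      std::sort(touched.begin(), touched.end());
      int best_c = old_c;
      double best_gain = -1e300;
      for (size_t t = 0; t < touched.size(); ++t) {
        int c = touched[t];
        double gain = wcomm[c] - stot[c] * k[i] / m2;
        if (gain > best_gain + 1e-12) { best_gain = gain; best_c = c; }
      }
      stot[best_c] += k[i];
      if (best_c != old_c) { comm[i] = best_c; improved = true; any_move = true; }
      for (size_t t = 0; t < touched.size(); ++t) wcomm[touched[t]] = 0.0;
    }
  }
  return any_move;
}

static void renumber(std::vector<int> &comm) {
  std::vector<int> map(comm.size(), -1);
  int next = 0;
  for (size_t i = 0; i < comm.size(); ++i) {
    if (map[comm[i]] < 0) map[comm[i]] = next++;
    comm[i] = map[comm[i]];
  }
}

static Graph aggregate(const Graph &g, const std::vector<int> &comm, int nc) {
  Graph h;
  h.n = nc;
  h.adj.assign(nc, std::vector<std::pair<int, double> >());
  h.selfw.assign(nc, 0.0);
  h.m = g.m;
  std::vector<std::map<int, double> > acc(nc);
  for (int i = 0; i < g.n; ++i) {
    h.selfw[comm[i]] += g.selfw[i];
    for (size_t t = 0; t < g.adj[i].size(); ++t) {
      int j = g.adj[i][t].first;
      if (j < i) continue;
      double w = g.adj[i][t].second;
      int ci = comm[i], cj = comm[j];
      if (ci == cj) h.selfw[ci] += w;
      else acc[std::min(ci, cj)][std::max(ci, cj)] += w;
    }
  }
  for (int c = 0; c < nc; ++c)
    for (std::map<int, double>::const_iterator it = acc[c].begin();
         it != acc[c].end(); ++it) {
      h.adj[c].push_back(std::make_pair(it->first, it->second));
      h.adj[it->first].push_back(std::make_pair(c, it->second));
    }
  return h;
}

// [[Rcpp::export(name = ".cpp_louvain")]]
List cpp_louvain(IntegerVector from, IntegerVector to, NumericVector weight,
                 int n_nodes, int seed, int n_restarts) {
  Graph g;
  g.n = n_nodes;
  g.adj.assign(n_nodes, std::vector<std::pair<int, double> >());
  g.selfw.assign(n_nodes, 0.0);
  g.m = 0.0;
  for (int e = 0; e < from.size(); ++e) {
    int u = from[e] - 1, v = to[e] - 1;
    double w = weight[e];
    g.m += w;
    if (u == v) { g.selfw[u] += w; continue; }
    g.adj[u].push_back(std::make_pair(v, w));
    g.adj[v].push_back(std::make_pair(u, w));
  }
  std::vector<int> best_comm(n_nodes);
  double best_q = -2.0;
  for (int r = 0; r < n_restarts; ++r) {
    std::mt19937 rng((uint32_t)seed + 1000003u * (uint32_t)r);
    std::vector<int> final_comm(n_nodes);
    for (int i = 0; i < n_nodes; ++i) final_comm[i] = i;
    Graph cur = g;
    std::vector<int> comm(cur.n);
    // even restarts: singleton start (classic Louvain); odd restarts:
    // random initial partition to diversify the basins reachable by the
    // greedy moves
    if (r % 2 == 0) {
      for (int i = 0; i < cur.n; ++i) comm[i] = i;
    } else {
      std::uniform_int_distribution<int> pick(0, std::max(1, cur.n / 2) - 1);
      for (int i = 0; i < cur.n; ++i) comm[i] = pick(rng);
    }
    while (true) {
      bool moved = one_level(cur, comm, rng);
      std::vector<int> cc = comm;
      renumber(cc);
      int nc = *std::max_element(cc.begin(), cc.end()) + 1;
      for (int i = 0; i < n_nodes; ++i) final_comm[i] = cc[final_comm[i]];
      if (!moved || nc == cur.n) break;
      cur = aggregate(cur, cc, nc);
      comm.resize(cur.n);
      for (int i = 0; i < cur.n; ++i) comm[i] = i;
    }
    double q = modularity_of(g, final_comm);
    if (q > best_q + 1e-12) { best_q = q; best_comm = final_comm; }
  }
  renumber(best_comm);
  IntegerVector membership(n_nodes);
  for (int i = 0; i < n_nodes; ++i) membership[i] = best_comm[i] + 1;
  return List::create(Named("membership") = membership,
                      Named("modularity") = best_q);
}
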