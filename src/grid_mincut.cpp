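#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <climits>
using namespace Rcpp;

// Minimum s-t cut on the 4-neighbour pixel grid used by the graph-cut
// segmentation stage, solved with Dinic's blocking-flow algorithm.
//
// Nodes are the nb x mb grid cells in column-major order, plus a source
// (foreground terminal) and a sink (background terminal). Capacities are
// integer-quantized by the caller.

namespace {

struct Dinic {
  struct Edge { int to; long long cap; };
  std::vector<Edge> edges;
  std::vector<std::vector<int>> adj;
  std::vector<int> level, iter;
  int n;

  explicit Dinic(int n_) : adj(n_), level(n_), iter(n_), n(n_) {}

  void add_edge(int u, int v, long long cap_uv, long long cap_vu) {
    adj[u].push_back(static_cast<int>(edges.size()));
    edges.push_back({v, cap_uv});
    adj[v].push_back(static_cast<int>(edges.size()));
    edges.push_back({u, cap_vu});
  }

  bool bfs(int s, int t) {
    std::fill(level.begin(), level.end(), -1);
    std::queue<int> q;
    level[s] = 0;
    q.push(s);
    while (!q.empty()) {
      int u = q.front();
      q.pop();
      for (int id : adj[u]) {
        const Edge &e = edges[id];
        if (e.cap > 0 && level[e.to] < 0) {
          level[e.to] = level[u] + 1;
          q.push(e.to);
        }
      }
    }
    return level[t] >= 0;
  }

  long long dfs(int u, int t, long long f) {
    if (u == t) return f;
    for (int &i = iter[u]; i < static_cast<int>(adj[u].size()); ++i) {
      int id = adj[u][i];
      Edge &e = edges[id];
      if (e.cap > 0 && level[e.to] == level[u] + 1) {
        long long d = dfs(e.to, t, std::min(f, e.cap));
        if (d > 0) {
          e.cap -= d;
          edges[id ^ 1].cap += d;
          return d;
        }
      }
    }
    return 0;
  }

  long long max_flow(int s, int t) {
    long long total = 0;
    while (bfs(s, t)) {
      std::fill(iter.begin(), iter.end(), 0);
      long long f;
      while ((f = dfs(s, t, LLONG_MAX)) > 0) total += f;
    }
    return total;
  }
};

}  // namespace

// [[Rcpp::export(name = ".grid_mincut")]]
List grid_mincut(int nb, int mb, NumericVector w_right, NumericVector w_down,
                 NumericVector src_cap, NumericVector sink_cap) {
  const int n = nb * mb;
  if (w_right.size() != static_cast<R_xlen_t>(nb) * (mb - 1) ||
      w_down.size() != static_cast<R_xlen_t>(nb - 1) * mb ||
      src_cap.size() != n || sink_cap.size() != n)
    stop("capacity vector lengths do not match the grid");

  const int S = n, T = n + 1;
  Dinic din(n + 2);
  din.edges.reserve(4 * static_cast<size_t>(n) + 2 * din.adj.size());

  // horizontal neighbour links: (r, c) -- (r, c + 1)
  for (int c = 0; c < mb - 1; ++c)
    for (int r = 0; r < nb; ++r) {
      long long w = static_cast<long long>(w_right[c * nb + r]);
      if (w > 0) din.add_edge(c * nb + r, (c + 1) * nb + r, w, w);
    }
  // vertical neighbour links: (r, c) -- (r + 1, c)
  for (int c = 0; c < mb; ++c)
    for (int r = 0; r < nb - 1; ++r) {
      long long w = static_cast<long long>(w_down[c * (nb - 1) + r]);
      if (w > 0) din.add_edge(c * nb + r, c * nb + r + 1, w, w);
    }
  // terminal links; only the difference matters for the cut, so the common
  // part of (source, sink) capacity is dropped to reduce the flow volume
  for (int i = 0; i < n; ++i) {
    long long s = static_cast<long long>(src_cap[i]);
    long long t = static_cast<long long>(sink_cap[i]);
    long long m = std::min(s, t);
    if (s - m > 0) din.add_edge(S, i, s - m, 0);
    if (t - m > 0) din.add_edge(i, T, t - m, 0);
  }

  long long flow = din.max_flow(S, T);

  // source side of the residual graph = foreground labels
  LogicalVector fg(n);
  std::vector<char> seen(n + 2, 0);
  std::queue<int> q;
  seen[S] = 1;
  q.push(S);
  while (!q.empty()) {
    int u = q.front();
    q.pop();
    for (int id : din.adj[u]) {
      const Dinic::Edge &e = din.edges[id];
      if (e.cap > 0 && !seen[e.to]) {
        seen[e.to] = 1;
        q.push(e.to);
      }
    }
  }
  for (int i = 0; i < n; ++i) fg[i] = seen[i] != 0;

  return List::create(_["foreground"] = fg,
                      _["flow"] = static_cast<double>(flow));
}
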