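#include <Rcpp.h>
using namespace Rcpp;

// Recursive probability diffusion. One unit of mass per anchor spreads to
// unvisited neighbours proportionally to |edge weight|. A node receiving
// mass m retains all of it when m < threshold or when it has no unvisited
// neighbours; otherwise it retains m/2 and spreads the other half onward.
// Node indices are 0-based; tie order is the row order of W (callers pass
// nodes in lexicographic id order).

struct Graph {
  int n;
  std::vector<std::vector<int>> nb;      // neighbour indices
  std::vector<std::vector<double>> wt;   // |weight| per neighbour

  explicit Graph(const NumericMatrix& W) : n(W.nrow()), nb(n), wt(n) {
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        if (W(i, j) > 0) {
          nb[i].push_back(j);
          wt[i].push_back(W(i, j));
        }
  }
};

struct Diffuser {
  const Graph& g;
  const std::vector<bool>& visited;
  double threshold;
  std::vector<double> score;

  Diffuser(const Graph& g_, const std::vector<bool>& visited_, double thr)
      : g(g_), visited(visited_), threshold(thr), score(g_.n, 0.0) {}

  double unvisited_weight(int v) const {
    double s = 0.0;
    const std::vector<int>& nb = g.nb[v];
    for (size_t k = 0; k < nb.size(); ++k)
      if (!visited[nb[k]]) s += g.wt[v][k];
    return s;
  }

  void receive(int v, double m) {
    double s = unvisited_weight(v);
    if (m < threshold || s <= 0) {
      score[v] += m;
      return;
    }
    score[v] += m / 2.0;
    double pass = m / 2.0;
    const std::vector<int>& nb = g.nb[v];
    for (size_t k = 0; k < nb.size(); ++k)
      if (!visited[nb[k]])
        receive(nb[k], pass * g.wt[v][k] / s);
  }

  void from_anchor(int a) {
    double s = unvisited_weight(a);
    if (s <= 0) return;  // isolated anchor: mass not delivered
    const std::vector<int>& nb = g.nb[a];
    for (size_t k = 0; k < nb.size(); ++k)
      if (!visited[nb[k]])
        receive(nb[k], g.wt[a][k] / s);
  }
};

// [[Rcpp::export(name = ".ctd_diffuse_cpp")]]
NumericVector ctd_diffuse_cpp(NumericMatrix W, IntegerVector anchors,
                              LogicalVector visited, double threshold) {
  Graph g(W);
  std::vector<bool> vis(g.n);
  for (int i = 0; i < g.n; ++i) vis[i] = visited[i];
  Diffuser d(g, vis, threshold);
  for (int k = 0; k < anchors.size(); ++k) d.from_anchor(anchors[k]);
  return NumericVector(d.score.begin(), d.score.end());
}

// Adaptive walk: rank nodes from `start`, re-anchoring on every member of S
// found along the way. Returns the ranking (0-based), the 1-based positions
// (after the start) at which members of S were found by diffusion, and the
// members of S never reached (appended to the ranking in id order).
static List walk_one(const Graph& g, const std::vector<bool>& in_set,
                     int start, double threshold) {
  int n = g.n;
  std::vector<bool> visited(n, false);
  std::vector<int> ranking;
  std::vector<int> anchors;
  std::vector<int> found_pos;

  int n_set = 0, n_found = 1;  // start counts as found
  for (int i = 0; i < n; ++i) if (in_set[i]) ++n_set;

  visited[start] = true;
  ranking.push_back(start);
  anchors.push_back(start);

  while ((int)ranking.size() < n && n_found < n_set) {
    Diffuser d(g, visited, threshold);
    for (size_t k = 0; k < anchors.size(); ++k) d.from_anchor(anchors[k]);
    int best = -1;
    double best_score = 0.0;
    for (int u = 0; u < n; ++u) {
      if (!visited[u] && d.score[u] > best_score) {
        best = u;
        best_score = d.score[u];  // ties keep the earlier (smaller id) node
      }
    }
    if (best < 0) break;  // disconnected remainder
    visited[best] = true;
    ranking.push_back(best);
    if (in_set[best]) {
      anchors.push_back(best);
      found_pos.push_back((int)ranking.size() - 1);  // position after start
      ++n_found;
    }
  }

  // unreached members of S, appended in id order
  std::vector<int> unreachable;
  for (int i = 0; i < n; ++i)
    if (in_set[i] && !visited[i]) {
      unreachable.push_back(i);
      ranking.push_back(i);
    }

  return List::create(Named("ranking") = IntegerVector(ranking.begin(), ranking.end()),
                      Named("found_pos") = IntegerVector(found_pos.begin(), found_pos.end()),
                      Named("unreachable") = IntegerVector(unreachable.begin(), unreachable.end()));
}

// [[Rcpp::export(name = ".ctd_walk_cpp")]]
List ctd_walk_cpp(NumericMatrix W, LogicalVector in_set, int start,
                  double threshold) {
  Graph g(W);
  std::vector<bool> s(g.n);
  for (int i = 0; i < g.n; ++i) s[i] = in_set[i];
  return walk_one(g, s, start, threshold);
}

// All walks for one set: one walk per start node, graph built once.
// [[Rcpp::export(name = ".ctd_walks_cpp")]]
List ctd_walks_cpp(NumericMatrix W, LogicalVector in_set,
                   IntegerVector starts, double threshold) {
  Graph g(W);
  std::vector<bool> s(g.n);
  for (int i = 0; i < g.n; ++i) s[i] = in_set[i];
  List out(starts.size());
  for (int k = 0; k < starts.size(); ++k)
    out[k] = walk_one(g, s, starts[k], threshold);
  return out;
}
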