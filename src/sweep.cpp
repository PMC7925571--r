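#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Adjacency-list Dijkstra (edge length = 1/weight) over the current graph.
// O(n) min-scan per pop; relaxation only over neighbours.
struct Graph {
  int n;
  std::vector<std::vector<int> > nbr;
  std::vector<std::vector<double> > wt;
  Graph(int n_) : n(n_), nbr(n_), wt(n_) {}
  void add_edge(int i, int j, double w) {
    nbr[i].push_back(j); wt[i].push_back(w);
    nbr[j].push_back(i); wt[j].push_back(w);
  }
};

static void dijkstra_adj(const Graph& g, int src, std::vector<double>& dist,
                         std::vector<char>& done) {
  int n = g.n;
  std::fill(dist.begin(), dist.end(), R_PosInf);
  std::fill(done.begin(), done.end(), 0);
  dist[src] = 0.0;
  for (int it = 0; it < n; ++it) {
    int u = -1; double best = R_PosInf;
    for (int v = 0; v < n; ++v)
      if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
    if (u < 0) break;
    done[u] = 1;
    const std::vector<int>& nb = g.nbr[u];
    const std::vector<double>& wv = g.wt[u];
    for (size_t a = 0; a < nb.size(); ++a) {
      int v = nb[a];
      if (!done[v]) {
        double nd = dist[u] + 1.0 / wv[a];
        if (nd < dist[v]) dist[v] = nd;
      }
    }
  }
}

// Dense-lookup Dijkstra on the subgraph induced by `idx` of the current
// weight matrix Wcur; returns the subgraph global efficiency.
static double subgraph_geff_dense(const std::vector<double>& Wcur, int n,
                                  const std::vector<int>& idx) {
  int k = (int)idx.size();
  if (k < 2) return 0.0;
  std::vector<double> dist(k);
  std::vector<char> done(k);
  double acc = 0.0;
  for (int s = 0; s < k; ++s) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    std::fill(done.begin(), done.end(), 0);
    dist[s] = 0.0;
    for (int it = 0; it < k; ++it) {
      int u = -1; double best = R_PosInf;
      for (int v = 0; v < k; ++v)
        if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
      if (u < 0) break;
      done[u] = 1;
      for (int v = 0; v < k; ++v) {
        if (done[v]) continue;
        double w = Wcur[idx[u] + (size_t)n * idx[v]];
        if (w > 0.0) {
          double nd = dist[u] + 1.0 / w;
          if (nd < dist[v]) dist[v] = nd;
        }
      }
    }
    for (int v = 0; v < k; ++v)
      if (v != s && R_finite(dist[v])) acc += 1.0 / dist[v];
  }
  return acc / ((double)k * (k - 1));
}

// Full proportional-threshold sweep for one subject in a single call.
// Edges are sorted once (strongest first, ties by ascending upper-triangle
// (row, col) index — identical to the R-level proportional_threshold rule)
// and added incrementally as the ascending sparsity grid admits more of
// them. For each threshold: global efficiency, characteristic path length
// over finite pairs (+ count of infinite ordered pairs; optionally binary
// hop-count path length), mean Onnela clustering, nodal local efficiency.
// [[Rcpp::export]]
List cpp_sweep_subject(NumericMatrix W, NumericVector thresholds,
                       bool hop_cpl = false, bool want_local = true,
                       bool want_clust = true) {
  int n = W.nrow();
  int nT = thresholds.size();
  struct Edge { double w; int i, j; };
  std::vector<Edge> edges;
  edges.reserve((size_t)n * (n - 1) / 2);
  for (int j = 1; j < n; ++j)
    for (int i = 0; i < j; ++i)
      if (W(i, j) > 0.0) edges.push_back(Edge{W(i, j), i, j});
  std::sort(edges.begin(), edges.end(), [](const Edge& a, const Edge& b) {
    if (a.w != b.w) return a.w > b.w;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });

  NumericVector ge(nT), cpl(nT), ninf(nT), mclust(nT);
  NumericMatrix leff(want_local ? n : 1, want_local ? nT : 1);

  std::vector<double> Wcur((size_t)n * n, 0.0), Wcbrt((size_t)n * n, 0.0);
  Graph g(n);
  std::vector<double> dist(n), dist2(n);
  std::vector<char> done(n);
  size_t added = 0;
  double total_pairs = (double)n * (n - 1) / 2.0;

  for (int t = 0; t < nT; ++t) {
    size_t k = (size_t)std::floor(thresholds[t] * total_pairs);
    if (k > edges.size()) k = edges.size();
    for (; added < k; ++added) {
      const Edge& e = edges[added];
      g.add_edge(e.i, e.j, e.w);
      Wcur[e.i + (size_t)n * e.j] = Wcur[e.j + (size_t)n * e.i] = e.w;
      double c = std::cbrt(e.w);
      Wcbrt[e.i + (size_t)n * e.j] = Wcbrt[e.j + (size_t)n * e.i] = c;
    }

    double inv_sum = 0.0, cpl_sum = 0.0;
    long n_inf = 0, n_fin = 0;
    for (int s = 0; s < n; ++s) {
      dijkstra_adj(g, s, dist, done);
      if (hop_cpl) {
        // hop counts: rerun with unit lengths
        std::fill(dist2.begin(), dist2.end(), R_PosInf);
        std::fill(done.begin(), done.end(), 0);
        dist2[s] = 0.0;
        for (int it = 0; it < n; ++it) {
          int u = -1; double best = R_PosInf;
          for (int v = 0; v < n; ++v)
            if (!done[v] && dist2[v] < best) { best = dist2[v]; u = v; }
          if (u < 0) break;
          done[u] = 1;
          for (size_t a = 0; a < g.nbr[u].size(); ++a) {
            int v = g.nbr[u][a];
            if (!done[v] && dist2[u] + 1.0 < dist2[v]) dist2[v] = dist2[u] + 1.0;
          }
        }
      }
      for (int v = 0; v < n; ++v) {
        if (v == s) continue;
        if (R_finite(dist[v])) inv_sum += 1.0 / dist[v];
        double dc = hop_cpl ? dist2[v] : dist[v];
        if (R_finite(dc)) { cpl_sum += dc; ++n_fin; } else ++n_inf;
      }
    }
    double denom = (double)n * (n - 1);
    ge[t] = n > 1 ? inv_sum / denom : 0.0;
    cpl[t] = n_fin > 0 ? cpl_sum / n_fin : R_PosInf;
    ninf[t] = (double)n_inf;

    if (want_clust) {
      double csum = 0.0;
      for (int i = 0; i < n; ++i) {
        int ki = (int)g.nbr[i].size();
        if (ki < 2) continue;
        double num = 0.0;
        for (size_t a = 0; a < g.nbr[i].size(); ++a) {
          int j = g.nbr[i][a];
          double wij = Wcbrt[i + (size_t)n * j];
          for (size_t b = 0; b < g.nbr[i].size(); ++b) {
            if (a == b) continue;
            int h = g.nbr[i][b];
            double wjh = Wcbrt[j + (size_t)n * h];
            if (wjh > 0.0) num += wij * wjh * Wcbrt[h + (size_t)n * i];
          }
        }
        csum += num / ((double)ki * (ki - 1));
      }
      mclust[t] = csum / n;
    }

    if (want_local) {
      std::vector<int> idx;
      for (int i = 0; i < n; ++i) {
        idx.assign(g.nbr[i].begin(), g.nbr[i].end());
        std::sort(idx.begin(), idx.end());
        leff(i, t) = idx.size() >= 2 ?
          subgraph_geff_dense(Wcur, n, idx) : 0.0;
      }
    }
  }
  return List::create(_["global_efficiency"] = ge,
                      _["char_path_length"] = cpl,
                      _["n_infinite_pairs"] = ninf,
                      _["mean_clustering"] = mclust,
                      _["local_efficiency"] = leff);
}
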