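#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Single-source shortest paths on a weighted graph where edge length is the
// reciprocal of the (positive) weight. O(n^2) scan-based Dijkstra: n <= 82
// here, so a heap buys nothing.
static void dijkstra_recip(const double* W, int n, int src,
                           std::vector<double>& dist,
                           std::vector<char>& done) {
  std::fill(dist.begin(), dist.end(), R_PosInf);
  std::fill(done.begin(), done.end(), 0);
  dist[src] = 0.0;
  for (int it = 0; it < n; ++it) {
    int u = -1;
    double best = R_PosInf;
    for (int v = 0; v < n; ++v)
      if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
    if (u < 0) break;
    done[u] = 1;
    const double du = dist[u];
    for (int v = 0; v < n; ++v) {
      double w = W[u + (size_t)n * v];
      if (w > 0.0 && !done[v]) {
        double nd = du + 1.0 / w;
        if (nd < dist[v]) dist[v] = nd;
      }
    }
  }
}

// All-pairs shortest path distances; unreachable pairs are +Inf.
// [[Rcpp::export]]
NumericMatrix cpp_shortest_distances(NumericMatrix W) {
  int n = W.nrow();
  NumericMatrix D(n, n);
  std::vector<double> dist(n);
  std::vector<char> done(n);
  for (int s = 0; s < n; ++s) {
    dijkstra_recip(W.begin(), n, s, dist, done);
    for (int v = 0; v < n; ++v) D(s, v) = dist[v];
    D(s, s) = 0.0;
  }
  return D;
}

// Global efficiency of the subgraph induced by `idx` (0-based) of W.
static double subgraph_geff(const double* W, int n,
                            const std::vector<int>& idx) {
  int k = (int)idx.size();
  if (k < 2) return 0.0;
  std::vector<double> S((size_t)k * k, 0.0);
  for (int a = 0; a < k; ++a)
    for (int b = 0; b < k; ++b)
      S[a + (size_t)k * b] = W[idx[a] + (size_t)n * idx[b]];
  std::vector<double> dist(k);
  std::vector<char> done(k);
  double acc = 0.0;
  for (int s = 0; s < k; ++s) {
    dijkstra_recip(S.data(), k, s, dist, done);
    for (int v = 0; v < k; ++v)
      if (v != s && R_finite(dist[v])) acc += 1.0 / dist[v];
  }
  return acc / ((double)k * (k - 1));
}

// [[Rcpp::export]]
double cpp_subgraph_geff(NumericMatrix W, IntegerVector idx0) {
  std::vector<int> idx(idx0.begin(), idx0.end());
  return subgraph_geff(W.begin(), W.nrow(), idx);
}

// One thresholded graph -> every per-threshold metric in a single pass:
// global efficiency, characteristic path length (finite pairs only, with the
// count of excluded infinite ordered pairs), Onnela clustering per node and
// its mean, and nodal local efficiency. `hop_cpl` switches the path-length
// numerator to binary hop counts (all edge lengths 1).
// [[Rcpp::export]]
List cpp_graph_metrics(NumericMatrix W, bool hop_cpl = false) {
  int n = W.nrow();
  const double* w = W.begin();
  std::vector<double> dist(n);
  std::vector<char> done(n);

  double inv_sum = 0.0, cpl_sum = 0.0;
  long n_inf = 0, n_fin = 0;

  std::vector<double> Wb;
  if (hop_cpl) {
    Wb.assign((size_t)n * n, 0.0);
    for (size_t i = 0; i < (size_t)n * n; ++i) Wb[i] = w[i] > 0.0 ? 1.0 : 0.0;
  }
  std::vector<double> dist2(n);

  for (int s = 0; s < n; ++s) {
    dijkstra_recip(w, n, s, dist, done);
    if (hop_cpl) dijkstra_recip(Wb.data(), n, s, dist2, done);
    for (int v = 0; v < n; ++v) {
      if (v == s) continue;
      if (R_finite(dist[v])) inv_sum += 1.0 / dist[v];
      double dcpl = hop_cpl ? dist2[v] : dist[v];
      if (R_finite(dcpl)) { cpl_sum += dcpl; ++n_fin; } else ++n_inf;
    }
  }
  double denom = (double)n * (n - 1);
  double geff = n > 1 ? inv_sum / denom : 0.0;
  double cpl = n_fin > 0 ? cpl_sum / n_fin : R_PosInf;

  // Onnela clustering: C_i = (1/(k_i(k_i-1))) * [Wc^3]_ii with Wc = W^(1/3).
  std::vector<double> Wc((size_t)n * n);
  for (size_t i = 0; i < (size_t)n * n; ++i) Wc[i] = std::cbrt(w[i]);
  NumericVector clust(n);
  IntegerVector degree(n);
  double clust_sum = 0.0;
  for (int i = 0; i < n; ++i) {
    int k = 0;
    for (int j = 0; j < n; ++j) if (w[i + (size_t)n * j] > 0.0) ++k;
    degree[i] = k;
    double ci = 0.0;
    if (k >= 2) {
      double num = 0.0;
      for (int j = 0; j < n; ++j) {
        double wij = Wc[i + (size_t)n * j];
        if (wij == 0.0) continue;
        for (int h = 0; h < n; ++h) {
          double wjh = Wc[j + (size_t)n * h];
          if (wjh == 0.0) continue;
          double whi = Wc[h + (size_t)n * i];
          if (whi > 0.0) num += wij * wjh * whi;
        }
      }
      ci = num / ((double)k * (k - 1));
    }
    clust[i] = ci;
    clust_sum += ci;
  }

  // Local efficiency: global efficiency of the neighbour-induced subgraph.
  NumericVector leff(n);
  std::vector<int> idx;
  for (int i = 0; i < n; ++i) {
    idx.clear();
    for (int j = 0; j < n; ++j) if (w[i + (size_t)n * j] > 0.0) idx.push_back(j);
    leff[i] = idx.size() >= 2 ? subgraph_geff(w, n, idx) : 0.0;
  }

  return List::create(
    _["global_efficiency"] = geff,
    _["char_path_length"] = cpl,
    _["n_infinite_pairs"] = (double)n_inf,
    _["clustering"] = clust,
    _["mean_clustering"] = clust_sum / n,
    _["local_efficiency"] = leff,
    _["degree"] = degree);
}
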