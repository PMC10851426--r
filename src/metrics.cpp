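// Binary undirected graph metrics for the density-sweep engine.
// Graphs arrive as a ranked edge list; each density keeps the first K edges,
// so the stack is nested by construction and the adjacency is grown in place.
// Distance-based metrics use word-parallel (bitset) BFS: the frontier is
// expanded by OR-ing 64-bit adjacency rows, and per-depth population counts
// give path-length sums without per-node distance arrays.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstdint>
using namespace Rcpp;

namespace {

inline int popcnt(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0;
  while (x) { x &= x - 1; ++c; }
  return c;
#endif
}

struct Graph {
  int n, W;                               // W = words per bit row
  std::vector<std::vector<int> > nbr;     // adjacency lists (Brandes)
  std::vector<uint64_t> bits;             // n x W adjacency bit rows
  explicit Graph(int n_)
      : n(n_), W((n_ + 63) / 64), nbr(n_), bits((size_t)n_ * W, 0) {}
  const uint64_t *row(int u) const { return &bits[(size_t)u * W]; }
  bool has(int u, int v) const {
    return (bits[(size_t)u * W + (v >> 6)] >> (v & 63)) & 1;
  }
  void add(int u, int v) {
    nbr[u].push_back(v);
    nbr[v].push_back(u);
    bits[(size_t)u * W + (v >> 6)] |= (uint64_t)1 << (v & 63);
    bits[(size_t)v * W + (u >> 6)] |= (uint64_t)1 << (u & 63);
  }
};

// bitset BFS from s restricted to 'mask' (mask must contain s); accumulates
// per-depth counts into sum_d (sum of distances) and sum_inv (sum of 1/d)
// over nodes reached from s, and returns the number reached (excluding s).
struct BfsScratch {
  std::vector<uint64_t> visited, frontier, next;
  void resize(int W) { visited.assign(W, 0); frontier.assign(W, 0); next.assign(W, 0); }
};

long bfs_bits(const Graph &g, int s, const uint64_t *mask, BfsScratch &sc,
              double &sum_d, double &sum_inv) {
  const int W = g.W;
  sc.resize(W);
  sc.visited[s >> 6] = (uint64_t)1 << (s & 63);
  sc.frontier[s >> 6] = sc.visited[s >> 6];
  long reached = 0;
  int depth = 0;
  bool more = true;
  while (more) {
    ++depth;
    for (int w = 0; w < W; ++w) sc.next[w] = 0;
    for (int w = 0; w < W; ++w) {
      uint64_t f = sc.frontier[w];
      while (f) {
        int u = (w << 6) + __builtin_ctzll(f);
        f &= f - 1;
        const uint64_t *r = g.row(u);
        for (int q = 0; q < W; ++q) sc.next[q] |= r[q];
      }
    }
    more = false;
    int cnt = 0;
    for (int w = 0; w < W; ++w) {
      uint64_t nw = sc.next[w] & ~sc.visited[w];
      if (mask) nw &= mask[w];
      sc.frontier[w] = nw;
      sc.visited[w] |= nw;
      if (nw) { more = true; cnt += popcnt(nw); }
    }
    if (cnt > 0) {
      reached += cnt;
      sum_d += (double)depth * cnt;
      sum_inv += (double)cnt / depth;
    }
  }
  return reached;
}

// Watts-Strogatz nodal clustering via bit-row intersections:
// sum_j in N(i) |N(i) & N(j)| counts each triangle at i twice.
void clustering_nodal(const Graph &g, std::vector<double> &cc) {
  for (int i = 0; i < g.n; ++i) {
    size_t k = g.nbr[i].size();
    if (k < 2) { cc[i] = 0.0; continue; }
    const uint64_t *ri = g.row(i);
    long twice_links = 0;
    for (size_t a = 0; a < k; ++a) {
      const uint64_t *rj = g.row(g.nbr[i][a]);
      for (int w = 0; w < g.W; ++w) twice_links += popcnt(ri[w] & rj[w]);
    }
    cc[i] = (double)twice_links / ((double)k * (k - 1));
  }
}

// Lp over finite ordered pairs, Eglobal with 1/inf = 0, nodal efficiency
void path_metrics(const Graph &g, double &lp, double &eglob,
                  std::vector<double> *ne) {
  BfsScratch sc;
  double sum_d = 0.0, sum_inv_all = 0.0;
  long n_finite = 0;
  for (int s = 0; s < g.n; ++s) {
    double sd = 0.0, si = 0.0;
    n_finite += bfs_bits(g, s, 0, sc, sd, si);
    sum_d += sd;
    sum_inv_all += si;
    if (ne) (*ne)[s] = (g.n > 1) ? si / (g.n - 1) : 0.0;
  }
  lp = (n_finite > 0) ? sum_d / n_finite : NA_REAL;
  eglob = (g.n > 1) ? sum_inv_all / ((double)g.n * (g.n - 1)) : 0.0;
}

// global efficiency of the subgraph induced by the neighbours of each node;
// BFS runs on the full bit rows masked to the neighbourhood, so no local
// re-indexing is needed.
void local_efficiency_nodal(const Graph &g, std::vector<double> &el) {
  BfsScratch sc;
  std::vector<uint64_t> mask(g.W);
  for (int i = 0; i < g.n; ++i) {
    size_t k = g.nbr[i].size();
    if (k < 2) { el[i] = 0.0; continue; }
    const uint64_t *ri = g.row(i);
    for (int w = 0; w < g.W; ++w) mask[w] = ri[w];
    double sum_inv = 0.0;
    for (size_t a = 0; a < k; ++a) {
      double sd = 0.0, si = 0.0;
      bfs_bits(g, g.nbr[i][a], mask.data(), sc, sd, si);
      sum_inv += si;
    }
    el[i] = sum_inv / ((double)k * (k - 1));
  }
}

// Brandes betweenness, undirected, unnormalized, each unordered pair once
void betweenness(const Graph &g, std::vector<double> &bc) {
  std::fill(bc.begin(), bc.end(), 0.0);
  std::vector<double> sigma(g.n), delta(g.n);
  std::vector<int> dist(g.n);
  std::vector<std::vector<int> > pred(g.n);
  std::vector<int> order;
  order.reserve(g.n);
  for (int s = 0; s < g.n; ++s) {
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(delta.begin(), delta.end(), 0.0);
    std::fill(dist.begin(), dist.end(), -1);
    for (int v = 0; v < g.n; ++v) pred[v].clear();
    order.clear();
    sigma[s] = 1.0; dist[s] = 0;
    std::queue<int> q;
    q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      order.push_back(u);
      for (size_t k = 0; k < g.nbr[u].size(); ++k) {
        int w = g.nbr[u][k];
        if (dist[w] < 0) { dist[w] = dist[u] + 1; q.push(w); }
        if (dist[w] == dist[u] + 1) { sigma[w] += sigma[u]; pred[w].push_back(u); }
      }
    }
    for (int idx = (int)order.size() - 1; idx >= 0; --idx) {
      int w = order[idx];
      for (size_t k = 0; k < pred[w].size(); ++k) {
        int u = pred[w][k];
        delta[u] += sigma[u] / sigma[w] * (1.0 + delta[w]);
      }
      if (w != s) bc[w] += delta[w];
    }
  }
  for (int v = 0; v < g.n; ++v) bc[v] *= 0.5;
}

double mean_vec(const std::vector<double> &x) {
  double s = 0.0;
  for (size_t i = 0; i < x.size(); ++i) s += x[i];
  return x.empty() ? 0.0 : s / x.size();
}

}  // namespace

// Metrics for every density of a nested stack. ei/ej: 1-based endpoints of
// edges ranked strongest-first; kvec: cumulative edge counts per density
// (non-decreasing). Flags select metric families; nodal adds per-node output.
// [[Rcpp::export]]
List stack_metrics_cpp(IntegerVector ei, IntegerVector ej, int n,
                       IntegerVector kvec, bool do_clust, bool do_path,
                       bool do_elocal, bool do_bc, bool nodal) {
  int nd = kvec.size();
  if (nd > 0 && kvec[nd - 1] > ei.size())
    stop("edge list shorter than largest requested edge count");
  Graph g(n);
  NumericVector C(nd, NA_REAL), Lp(nd, NA_REAL), Eg(nd, NA_REAL), El(nd, NA_REAL);
  NumericMatrix BC = do_bc && nodal ? NumericMatrix(n, nd) : NumericMatrix(0, 0);
  NumericMatrix NE = do_path && nodal ? NumericMatrix(n, nd) : NumericMatrix(0, 0);
  IntegerMatrix DC = nodal ? IntegerMatrix(n, nd) : IntegerMatrix(0, 0);
  std::vector<double> buf(n), nebuf(n);
  int added = 0;
  for (int d = 0; d < nd; ++d) {
    int K = kvec[d];
    if (K < added) stop("edge counts must be non-decreasing across densities");
    for (; added < K; ++added) {
      int u = ei[added] - 1, v = ej[added] - 1;
      if (u < 0 || u >= n || v < 0 || v >= n || u == v)
        stop("invalid edge endpoint");
      if (g.has(u, v)) stop("duplicate edge in ranked list");
      g.add(u, v);
    }
    if (do_clust) { clustering_nodal(g, buf); C[d] = mean_vec(buf); }
    if (do_path) {
      double lp, eg;
      path_metrics(g, lp, eg, nodal ? &nebuf : (std::vector<double> *)0);
      Lp[d] = lp; Eg[d] = eg;
      if (nodal) for (int i = 0; i < n; ++i) NE(i, d) = nebuf[i];
    }
    if (do_elocal) { local_efficiency_nodal(g, buf); El[d] = mean_vec(buf); }
    if (do_bc && nodal) {
      betweenness(g, buf);
      for (int i = 0; i < n; ++i) BC(i, d) = buf[i];
    }
    if (nodal)
      for (int i = 0; i < n; ++i) DC(i, d) = (int)g.nbr[i].size();
  }
  return List::create(_["C"] = C, _["Lp"] = Lp, _["Eglobal"] = Eg,
                      _["Elocal"] = El, _["BC"] = BC, _["DC"] = DC,
                      _["NE"] = NE);
}

// Full metric set for a single adjacency matrix (exported R helpers).
// [[Rcpp::export]]
List graph_metrics_cpp(IntegerMatrix adj) {
  int n = adj.nrow();
  if (adj.ncol() != n) stop("adjacency must be square");
  Graph g(n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (adj(i, j) != 0) g.add(i, j);
  std::vector<double> cc(n), el(n), bc(n), ne(n);
  double lp, eg;
  clustering_nodal(g, cc);
  path_metrics(g, lp, eg, &ne);
  local_efficiency_nodal(g, el);
  betweenness(g, bc);
  IntegerVector deg(n);
  for (int i = 0; i < n; ++i) deg[i] = (int)g.nbr[i].size();
  return List::create(
      _["C"] = mean_vec(cc), _["C_nodal"] = NumericVector(cc.begin(), cc.end()),
      _["Lp"] = lp, _["Eglobal"] = eg,
      _["Elocal"] = mean_vec(el),
      _["Elocal_nodal"] = NumericVector(el.begin(), el.end()),
      _["BC"] = NumericVector(bc.begin(), bc.end()), _["DC"] = deg,
      _["NE"] = NumericVector(ne.begin(), ne.end()));
}
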