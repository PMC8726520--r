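#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Alias method for O(1) draws from a discrete distribution.
struct AliasTable {
  std::vector<double> prob;
  std::vector<int> alias;
  void build(const std::vector<double>& w) {
    int n = w.size();
    prob.assign(n, 0.0);
    alias.assign(n, 0);
    double sum = 0.0;
    for (double x : w) sum += x;
    std::vector<double> p(n);
    for (int i = 0; i < n; ++i) p[i] = w[i] * n / sum;
    std::vector<int> small, large;
    for (int i = 0; i < n; ++i) (p[i] < 1.0 ? small : large).push_back(i);
    while (!small.empty() && !large.empty()) {
      int s = small.back(); small.pop_back();
      int l = large.back(); large.pop_back();
      prob[s] = p[s];
      alias[s] = l;
      p[l] = p[l] + p[s] - 1.0;
      (p[l] < 1.0 ? small : large).push_back(l);
    }
    for (int s : small) prob[s] = 1.0;
    for (int l : large) prob[l] = 1.0;
  }
  template <class RNG>
  int draw(RNG& rng) const {
    int n = prob.size();
    double u = rng.unif() * n;
    int i = (int)u;
    if (i >= n) i = n - 1;
    return (u - i) < prob[i] ? i : alias[i];
  }
};

// Deterministic 64-bit xorshift RNG so results do not depend on the
// platform's std::mt19937 distribution implementations.
struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  double unif() {  // in [0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
};

static inline double sigmoid_clamped(double x) {
  if (x > 35.0) x = 35.0;
  if (x < -35.0) x = -35.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Edge-sampling SGD for LINE.
//
// order = 1: vertex-vertex model over undirected edges (each draw is
// oriented at random); context == vertex matrix.
// order = 2: vertex-context model; undirected edges are expanded to two
// directed edges by the caller.
//
// Negatives drawn proportional to degree^neg_power.  Learning rate decays
// linearly from lr0 to lr0/100.  Embedding matrices are dim x n_nodes
// (one column per node, matching R's column-major storage).  Returns the
// vertex matrix, the context matrix (order 2) and a running-mean trace of
// the sampled objective.
// [[Rcpp::export(name = ".line_sgd")]]
List line_sgd(IntegerVector src, IntegerVector dst, NumericVector weight,
              int n_nodes, int dim, double n_samples, int K,
              double lr0, int order, double neg_power, int seed,
              NumericMatrix init_vertex, NumericMatrix init_context) {
  const int m = src.size();
  if (m == 0) stop("no edges");
  XorShift rng((uint64_t)seed * 2654435761ULL + 1ULL);

  AliasTable edge_tab;
  {
    std::vector<double> w(weight.begin(), weight.end());
    edge_tab.build(w);
  }
  std::vector<double> deg(n_nodes, 0.0);
  for (int e = 0; e < m; ++e) {
    deg[src[e]] += weight[e];
    deg[dst[e]] += weight[e];
  }
  AliasTable neg_tab;
  {
    std::vector<double> w(n_nodes);
    for (int i = 0; i < n_nodes; ++i) w[i] = std::pow(deg[i], neg_power);
    neg_tab.build(w);
  }

  std::vector<double> vert(init_vertex.begin(), init_vertex.end());
  std::vector<double> ctx;
  if (order == 2) ctx.assign(init_context.begin(), init_context.end());
  double* V = vert.data();
  double* C = (order == 2) ? ctx.data() : vert.data();

  const long total = (long)n_samples;
  const int trace_len = 100;
  NumericVector trace(trace_len);
  std::vector<double> block_loss(trace_len, 0.0);
  std::vector<long> block_n(trace_len, 0);
  std::vector<double> acc(dim);

  for (long t = 0; t < total; ++t) {
    double lr = lr0 * (1.0 - 0.99 * (double)t / (double)total);
    int e = edge_tab.draw(rng);
    int a = src[e], b = dst[e];
    if (order == 1 && rng.unif() < 0.5) std::swap(a, b);
    double* ua = V + (size_t)a * dim;
    std::fill(acc.begin(), acc.end(), 0.0);
    double loss = 0.0;
    for (int k = 0; k <= K; ++k) {
      int tgt;
      double label;
      if (k == 0) { tgt = b; label = 1.0; }
      else {
        tgt = neg_tab.draw(rng);
        if (tgt == a || tgt == b) { continue; }
        label = 0.0;
      }
      double* ct = C + (size_t)tgt * dim;
      double dot = 0.0;
      for (int d = 0; d < dim; ++d) dot += ua[d] * ct[d];
      double p = sigmoid_clamped(dot);
      loss -= (label > 0.5) ? std::log(p + 1e-15) : std::log(1.0 - p + 1e-15);
      double g = lr * (label - p);
      for (int d = 0; d < dim; ++d) {
        acc[d] += g * ct[d];
        ct[d] += g * ua[d];
      }
    }
    for (int d = 0; d < dim; ++d) ua[d] += acc[d];
    int blk = (int)((double)t * trace_len / (double)total);
    if (blk >= trace_len) blk = trace_len - 1;
    block_loss[blk] += loss;
    block_n[blk] += 1;
  }
  for (int i = 0; i < trace_len; ++i)
    trace[i] = block_n[i] > 0 ? block_loss[i] / block_n[i] : NA_REAL;

  for (double x : vert)
    if (!std::isfinite(x))
      stop("non-finite embedding entry (lr0 = %f)", lr0);
  NumericMatrix out_v(dim, n_nodes);
  std::copy(vert.begin(), vert.end(), out_v.begin());
  List out = List::create(Named("vertex") = out_v,
                          Named("trace") = trace);
  if (order == 2) {
    NumericMatrix out_c(dim, n_nodes);
    std::copy(ctx.begin(), ctx.end(), out_c.begin());
    out["context"] = out_c;
  }
  return out;
}
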