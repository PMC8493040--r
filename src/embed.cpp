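// Skip-gram with negative sampling (word2vec-style) over walk corpora, and
// LINE edge-sampling training. Single-threaded with an internal xorshift RNG
// so runs are bitwise reproducible for a given seed.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed * 2685821657736338717ULL + 1ULL) {}
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s;
  }
  double unif() {  // in [0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  int randint(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Cumulative table for unigram^0.75 negative sampling; draw by binary search.
struct NegTable {
  std::vector<double> cum;
  double total;
  explicit NegTable(const std::vector<double>& counts) {
    cum.resize(counts.size());
    double acc = 0.0;
    for (size_t i = 0; i < counts.size(); ++i) {
      acc += std::pow(counts[i], 0.75);
      cum[i] = acc;
    }
    total = acc;
  }
  int draw(XorShift& rng) const {
    double u = rng.unif() * total;
    return static_cast<int>(
        std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
  }
};

}  // namespace

// [[Rcpp::export]]
NumericMatrix sgns_train_cpp(List walks, int n_nodes, int dim, int window,
                             int epochs, int negative, double alpha,
                             int seed) {
  std::vector<std::vector<int>> corpus;
  corpus.reserve(walks.size());
  std::vector<double> counts(n_nodes, 0.0);
  long long n_tokens = 0;
  for (R_xlen_t i = 0; i < walks.size(); ++i) {
    IntegerVector w = walks[i];
    std::vector<int> v(w.size());
    for (R_xlen_t j = 0; j < w.size(); ++j) {
      v[j] = w[j] - 1;  // to 0-based
      counts[v[j]] += 1.0;
    }
    n_tokens += w.size();
    corpus.push_back(std::move(v));
  }
  XorShift rng(static_cast<uint64_t>(seed) + 0x9E3779B97F4A7C15ULL);
  NegTable neg(counts);

  std::vector<double> syn0(static_cast<size_t>(n_nodes) * dim);
  std::vector<double> syn1(static_cast<size_t>(n_nodes) * dim, 0.0);
  for (auto& v : syn0) v = (rng.unif() - 0.5) / dim;

  const double min_lr = alpha * 1e-4;
  const long long total = n_tokens * std::max(epochs, 1);
  long long processed = 0;
  std::vector<double> err(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (const auto& walk : corpus) {
      int len = static_cast<int>(walk.size());
      for (int t = 0; t < len; ++t) {
        ++processed;
        double lr = alpha * (1.0 - static_cast<double>(processed) / (total + 1));
        if (lr < min_lr) lr = min_lr;
        int cur = walk[t];
        int b = rng.randint(window);  // dynamic window shrink, as in word2vec
        for (int off = b - window; off <= window - b; ++off) {
          if (off == 0) continue;
          int pos = t + off;
          if (pos < 0 || pos >= len) continue;
          int ctx = walk[pos];
          double* v_in = &syn0[static_cast<size_t>(cur) * dim];
          std::fill(err.begin(), err.end(), 0.0);
          for (int k = 0; k <= negative; ++k) {
            int target;
            double label;
            if (k == 0) {
              target = ctx;
              label = 1.0;
            } else {
              target = neg.draw(rng);
              if (target == ctx) continue;
              label = 0.0;
            }
            double* v_out = &syn1[static_cast<size_t>(target) * dim];
            double f = 0.0;
            for (int d = 0; d < dim; ++d) f += v_in[d] * v_out[d];
            double g = (label - sigmoid(f)) * lr;
            for (int d = 0; d < dim; ++d) {
              err[d] += g * v_out[d];
              v_out[d] += g * v_in[d];
            }
          }
          for (int d = 0; d < dim; ++d) v_in[d] += err[d];
        }
      }
    }
  }

  NumericMatrix out(n_nodes, dim);
  for (int i = 0; i < n_nodes; ++i)
    for (int d = 0; d < dim; ++d)
      out(i, d) = syn0[static_cast<size_t>(i) * dim + d];
  return out;
}

// [[Rcpp::export]]
NumericMatrix line_train_cpp(IntegerMatrix edges, int n_nodes, int dim,
                             int order, double n_samples, int negative,
                             double alpha, int seed) {
  int m = edges.nrow();
  std::vector<double> deg(n_nodes, 0.0);
  for (int i = 0; i < m; ++i) {
    deg[edges(i, 0) - 1] += 1.0;
    deg[edges(i, 1) - 1] += 1.0;
  }
  XorShift rng(static_cast<uint64_t>(seed) * 31ULL + 0xA24BAED4963EE407ULL);
  NegTable neg(deg);

  std::vector<double> emb(static_cast<size_t>(n_nodes) * dim);
  for (auto& v : emb) v = (rng.unif() - 0.5) / dim;
  // first order: targets share the embedding matrix; second order: separate
  // context vectors.
  std::vector<double> ctx;
  if (order == 2) ctx.assign(static_cast<size_t>(n_nodes) * dim, 0.0);
  std::vector<double>& tgt = (order == 2) ? ctx : emb;

  const double min_lr = alpha * 1e-4;
  const long long total = static_cast<long long>(n_samples);
  std::vector<double> err(dim);

  for (long long s = 0; s < total; ++s) {
    double lr = alpha * (1.0 - static_cast<double>(s) / (total + 1));
    if (lr < min_lr) lr = min_lr;
    int e = rng.randint(m);
    int u = edges(e, 0) - 1;
    int v = edges(e, 1) - 1;
    if (rng.unif() < 0.5) std::swap(u, v);  // undirected: train both directions
    double* v_in = &emb[static_cast<size_t>(u) * dim];
    std::fill(err.begin(), err.end(), 0.0);
    for (int k = 0; k <= negative; ++k) {
      int target;
      double label;
      if (k == 0) {
        target = v;
        label = 1.0;
      } else {
        target = neg.draw(rng);
        if (target == v || target == u) continue;
        label = 0.0;
      }
      double* v_out = &tgt[static_cast<size_t>(target) * dim];
      double f = 0.0;
      for (int d = 0; d < dim; ++d) f += v_in[d] * v_out[d];
      double g = (label - sigmoid(f)) * lr;
      for (int d = 0; d < dim; ++d) {
        err[d] += g * v_out[d];
        v_out[d] += g * v_in[d];
      }
    }
    for (int d = 0; d < dim; ++d) v_in[d] += err[d];
  }

  NumericMatrix out(n_nodes, dim);
  for (int i = 0; i < n_nodes; ++i)
    for (int d = 0; d < dim; ++d)
      out(i, d) = emb[static_cast<size_t>(i) * dim + d];
  return out;
}
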