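#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// splitmix64 seeded xorshift128+ — deterministic, independent of R's RNG
struct Rng {
  uint64_t s0, s1;
  explicit Rng(uint64_t seed) {
    uint64_t z = seed + 0x9e3779b97f4a7c15ULL;
    auto sm = [&z]() {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t x = z;
      x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
      x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
      return x ^ (x >> 31);
    };
    s0 = sm(); s1 = sm();
    if (s0 == 0 && s1 == 0) s0 = 1;
  }
  uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int unif_int(int n) { return (int)(unif() * n) % n; }
};

static bool adjacent(const std::vector<int>& adj, const std::vector<int>& off,
                     int u, int v) {
  // neighbors of u are sorted; binary search for v
  return std::binary_search(adj.begin() + off[u], adj.begin() + off[u + 1], v);
}

// Second-order biased random walks. adj/off: 0-based CSR (sorted neighbor
// lists), w: edge weights aligned with adj. Returns a list of integer
// vectors of 1-based node indices; walks_per_node walks start at every node.
// [[Rcpp::export]]
List cpp_generate_walks(IntegerVector adj_, IntegerVector off_,
                        NumericVector w_, double p, double q,
                        int walk_length, int walks_per_node, double seed) {
  std::vector<int> adj(adj_.begin(), adj_.end());
  std::vector<int> off(off_.begin(), off_.end());
  std::vector<double> w(w_.begin(), w_.end());
  int n = off.size() - 1;
  Rng rng((uint64_t)seed);
  List walks(n * walks_per_node);
  std::vector<double> cum;
  int k = 0;
  for (int r = 0; r < walks_per_node; ++r) {
    for (int s = 0; s < n; ++s) {
      std::vector<int> walk;
      walk.reserve(walk_length);
      walk.push_back(s);
      int deg = off[s + 1] - off[s];
      if (deg > 0) {
        // first step: uniform over neighbors (no predecessor yet)
        int curr = adj[off[s] + rng.unif_int(deg)];
        int prev = s;
        walk.push_back(curr);
        while ((int)walk.size() < walk_length) {
          int d = off[curr + 1] - off[curr];
          if (d == 0) break;
          cum.resize(d);
          double tot = 0.0;
          for (int i = 0; i < d; ++i) {
            int x = adj[off[curr] + i];
            double a;
            if (x == prev) a = 1.0 / p;
            else if (adjacent(adj, off, prev, x)) a = 1.0;
            else a = 1.0 / q;
            tot += a * w[off[curr] + i];
            cum[i] = tot;
          }
          double u = rng.unif() * tot;
          int i = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
          if (i >= d) i = d - 1;
          int nxt = adj[off[curr] + i];
          walk.push_back(nxt);
          prev = curr;
          curr = nxt;
        }
      }
      IntegerVector wv(walk.size());
      for (size_t i = 0; i < walk.size(); ++i) wv[i] = walk[i] + 1;
      walks[k++] = wv;
    }
  }
  return walks;
}

// Skip-gram with negative sampling over walk sequences (word2vec-style):
// dynamic window, unigram^0.75 negative table, linearly decaying learning
// rate. Single-threaded and fully deterministic given seed.
// [[Rcpp::export]]
NumericMatrix cpp_train_sgns(List walks, int n_nodes, int dim, int window,
                             int epochs, int negative, double alpha,
                             double seed) {
  Rng rng((uint64_t)seed);
  std::vector<std::vector<int>> seqs;
  seqs.reserve(walks.size());
  std::vector<double> cnt(n_nodes, 0.0);
  long long total_tokens = 0;
  for (int i = 0; i < walks.size(); ++i) {
    IntegerVector wv = walks[i];
    std::vector<int> s(wv.size());
    for (int j = 0; j < wv.size(); ++j) {
      s[j] = wv[j] - 1;
      cnt[s[j]] += 1.0;
      ++total_tokens;
    }
    seqs.push_back(std::move(s));
  }
  if (total_tokens == 0) stop("empty walk corpus");

  // cumulative unigram^0.75 table for negative sampling
  std::vector<double> neg_cum(n_nodes);
  double tot = 0.0;
  for (int i = 0; i < n_nodes; ++i) {
    tot += std::pow(cnt[i], 0.75);
    neg_cum[i] = tot;
  }

  std::vector<double> syn0((size_t)n_nodes * dim);
  std::vector<double> syn1((size_t)n_nodes * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  // precomputed logistic table on [-6, 6] (word2vec-style); saturates outside
  const int EXP_N = 1000; const double EXP_MAX = 6.0;
  std::vector<double> exp_table(EXP_N);
  for (int i = 0; i < EXP_N; ++i) {
    double z = (2.0 * i / EXP_N - 1.0) * EXP_MAX;
    exp_table[i] = 1.0 / (1.0 + std::exp(-z));
  }
  auto sigmoid = [&](double z) {
    if (z >= EXP_MAX) return 1.0;
    if (z <= -EXP_MAX) return 0.0;
    return exp_table[(int)((z + EXP_MAX) * (EXP_N / (2.0 * EXP_MAX)))];
  };

  const double min_alpha_frac = 1e-4;
  long long processed = 0, budget = (long long)epochs * total_tokens;
  std::vector<double> grad(dim);
  std::vector<char> updated(n_nodes, 0);
  for (int ep = 0; ep < epochs; ++ep) {
    for (const auto& s : seqs) {
      int len = (int)s.size();
      for (int pos = 0; pos < len; ++pos) {
        double frac = (double)processed / (double)budget;
        double lr = alpha * std::max(1.0 - frac, min_alpha_frac);
        ++processed;
        int b = rng.unif_int(window) + 1; // dynamic window in [1, window]
        int center = s[pos];
        for (int off2 = -b; off2 <= b; ++off2) {
          if (off2 == 0) continue;
          int cp = pos + off2;
          if (cp < 0 || cp >= len) continue;
          int ctx = s[cp];
          double* v = &syn0[(size_t)ctx * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int d = 0; d < negative + 1; ++d) {
            int target; double lab;
            if (d == 0) { target = center; lab = 1.0; }
            else {
              double u = rng.unif() * tot;
              target = (int)(std::lower_bound(neg_cum.begin(), neg_cum.end(), u)
                             - neg_cum.begin());
              if (target >= n_nodes) target = n_nodes - 1;
              if (target == center) continue;
              lab = 0.0;
            }
            double* o = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int j = 0; j < dim; ++j) dot += v[j] * o[j];
            double pred = sigmoid(dot);
            double g = (lab - pred) * lr;
            for (int j = 0; j < dim; ++j) { grad[j] += g * o[j]; o[j] += g * v[j]; }
          }
          for (int j = 0; j < dim; ++j) v[j] += grad[j];
          updated[ctx] = 1;
        }
      }
    }
  }
  NumericMatrix out(n_nodes, dim);
  for (int i = 0; i < n_nodes; ++i) {
    // nodes absent from the corpus, or never co-occurring with anything
    // (length-1 walks of isolated nodes), keep a zero vector
    if (cnt[i] == 0.0 || !updated[i]) continue;
    for (int j = 0; j < dim; ++j) out(i, j) = syn0[(size_t)i * dim + j];
  }
  return out;
}

// Windowed co-occurrence counts over walks (symmetric), for the PPMI+SVD
// embedding backend. Returns a dense matrix; graphs here are small.
// [[Rcpp::export]]
NumericMatrix cpp_cooccurrence(List walks, int n_nodes, int window) {
  NumericMatrix M(n_nodes, n_nodes);
  for (int i = 0; i < walks.size(); ++i) {
    IntegerVector wv = walks[i];
    int len = wv.size();
    for (int pos = 0; pos < len; ++pos) {
      int a = wv[pos] - 1;
      for (int off = 1; off <= window; ++off) {
        int cp = pos + off;
        if (cp >= len) break;
        int b = wv[cp] - 1;
        M(a, b) += 1.0;
        M(b, a) += 1.0;
      }
    }
  }
  return M;
}
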