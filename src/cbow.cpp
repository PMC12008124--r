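// Continuous bag-of-words word2vec with negative sampling.
// Single-threaded and seeded, so embeddings are bit-reproducible.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

// xorshift64* PRNG: deterministic across platforms, unlike std::mt19937
// whose distribution implementations vary by standard library.
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 88172645463325252ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 2685821657736338717ULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int index(int n) { return (int)(unif() * n) % n; }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// [[Rcpp::export(name = ".cbow_train")]]
NumericMatrix cbow_train(List docs, int vocab, int dim, int window,
                         int epochs, int negative, double alpha0,
                         int seed) {
  Rng rng((uint64_t)seed * 2654435761ULL + 1ULL);

  // token counts -> unigram table with the classic 0.75 power
  std::vector<double> cnt(vocab, 0.0);
  long long total_pos = 0;
  for (R_xlen_t d = 0; d < docs.size(); ++d) {
    IntegerVector doc = docs[d];
    total_pos += doc.size();
    for (int i = 0; i < doc.size(); ++i) {
      if (doc[i] < 0 || doc[i] >= vocab) stop("token id out of range");
      cnt[doc[i]] += 1.0;
    }
  }
  if (total_pos == 0) stop("empty corpus");
  const int table_size = 100000;
  std::vector<int> table(table_size);
  double z = 0.0;
  for (int v = 0; v < vocab; ++v) z += std::pow(cnt[v], 0.75);
  {
    int v = 0;
    double cum = std::pow(cnt[0], 0.75) / z;
    for (int t = 0; t < table_size; ++t) {
      table[t] = v;
      if ((t + 1.0) / table_size > cum && v < vocab - 1) {
        ++v;
        cum += std::pow(cnt[v], 0.75) / z;
      }
    }
  }

  // init: input vectors small uniform, output vectors zero (word2vec.c)
  std::vector<double> syn0((size_t)vocab * dim), syn1((size_t)vocab * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  std::vector<double> h(dim), grad(dim);
  const double alpha_min = 1e-4;
  long long done = 0, total = (long long)epochs * total_pos;

  for (int ep = 0; ep < epochs; ++ep) {
    for (R_xlen_t d = 0; d < docs.size(); ++d) {
      IntegerVector doc = docs[d];
      int n = doc.size();
      for (int t = 0; t < n; ++t, ++done) {
        double alpha = alpha0 * (1.0 - (double)done / (double)(total + 1));
        if (alpha < alpha_min) alpha = alpha_min;
        int lo = t - window < 0 ? 0 : t - window;
        int hi = t + window >= n ? n - 1 : t + window;
        int nctx = hi - lo;  // excludes the center token
        if (nctx <= 0) continue;
        std::fill(h.begin(), h.end(), 0.0);
        for (int c = lo; c <= hi; ++c) {
          if (c == t) continue;
          const double* v0 = &syn0[(size_t)doc[c] * dim];
          for (int k = 0; k < dim; ++k) h[k] += v0[k];
        }
        for (int k = 0; k < dim; ++k) h[k] /= nctx;
        std::fill(grad.begin(), grad.end(), 0.0);
        int center = doc[t];
        for (int s = 0; s <= negative; ++s) {
          int target; double label;
          if (s == 0) { target = center; label = 1.0; }
          else {
            target = table[rng.index(table_size)];
            if (target == center) continue;
            label = 0.0;
          }
          double* v1 = &syn1[(size_t)target * dim];
          double f = 0.0;
          for (int k = 0; k < dim; ++k) f += h[k] * v1[k];
          double g = (label - sigmoid(f)) * alpha;
          for (int k = 0; k < dim; ++k) {
            grad[k] += g * v1[k];
            v1[k] += g * h[k];
          }
        }
        for (int c = lo; c <= hi; ++c) {
          if (c == t) continue;
          double* v0 = &syn0[(size_t)doc[c] * dim];
          for (int k = 0; k < dim; ++k) v0[k] += grad[k] / nctx;
        }
      }
    }
  }

  NumericMatrix out(vocab, dim);
  for (int v = 0; v < vocab; ++v)
    for (int k = 0; k < dim; ++k) out(v, k) = syn0[(size_t)v * dim + k];
  return out;
}
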