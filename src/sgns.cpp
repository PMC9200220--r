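#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

// Skip-gram with negative sampling, single-threaded, self-contained RNG so
// results are bit-reproducible for a given seed regardless of R's RNG state.

namespace {

struct XorShift64 {
  uint64_t s;
  explicit XorShift64(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

inline double sigmoidc(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// [[Rcpp::export(name = ".sgns_train_cpp")]]
Rcpp::NumericMatrix sgns_train_cpp(Rcpp::IntegerVector corpus,
                                   Rcpp::IntegerVector sent_len,
                                   int vocab, int dim, int window,
                                   int negative, int epochs, double lr,
                                   Rcpp::NumericVector unigram,
                                   double seed) {
  std::vector<double> syn0(static_cast<size_t>(vocab) * dim);
  std::vector<double> syn1(static_cast<size_t>(vocab) * dim, 0.0);
  XorShift64 rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  // cumulative unigram^alpha table for negative sampling
  std::vector<double> cum(vocab);
  double tot = 0.0;
  for (int v = 0; v < vocab; ++v) { tot += unigram[v]; cum[v] = tot; }
  for (int v = 0; v < vocab; ++v) cum[v] /= tot;

  auto sample_neg = [&]() {
    double u = rng.unif();
    int lo = 0, hi = vocab - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cum[mid] < u) lo = mid + 1; else hi = mid;
    }
    return lo;
  };

  std::vector<double> grad(dim);
  int n_sent = sent_len.size();
  for (int ep = 0; ep < epochs; ++ep) {
    int offset = 0;
    for (int s = 0; s < n_sent; ++s) {
      int len = sent_len[s];
      for (int t = 0; t < len; ++t) {
        int w = corpus[offset + t];
        int b = rng.below(window) ;  // dynamic window shrink as in word2vec
        for (int c = t - window + b; c <= t + window - b; ++c) {
          if (c == t || c < 0 || c >= len) continue;
          int ctx = corpus[offset + c];
          double* v_in = &syn0[static_cast<size_t>(w) * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int k = 0; k <= negative; ++k) {
            int target; double label;
            if (k == 0) { target = ctx; label = 1.0; }
            else {
              target = sample_neg();
              if (target == ctx) continue;
              label = 0.0;
            }
            double* v_out = &syn1[static_cast<size_t>(target) * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += v_in[d] * v_out[d];
            double g = (label - sigmoidc(dot)) * lr;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * v_out[d];
              v_out[d] += g * v_in[d];
            }
          }
          for (int d = 0; d < dim; ++d) v_in[d] += grad[d];
        }
      }
      offset += len;
    }
  }

  Rcpp::NumericMatrix out(vocab, dim);
  for (int v = 0; v < vocab; ++v)
    for (int d = 0; d < dim; ++d)
      out(v, d) = syn0[static_cast<size_t>(v) * dim + d];
  return out;
}
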