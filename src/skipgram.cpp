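// Skip-gram with negative sampling over random-walk corpora.
// Deterministic: all randomness comes from an internal xorshift64* generator
// seeded from R, independent of R's RNG and of thread scheduling (single
// threaded by construction).
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static inline uint64_t xorshift(uint64_t &s) {
  s ^= s << 13;
  s ^= s >> 7;
  s ^= s << 17;
  return s * 0x2545F4914F6CDD1DULL;
}

static inline double runif01(uint64_t &s) {
  return (xorshift(s) >> 11) * (1.0 / 9007199254740992.0);
}

// [[Rcpp::export(name = ".skipgramSGNS")]]
NumericMatrix skipgram_sgns(List walks, int vocab, int dim, int window,
                            int epochs, int negative, double alpha0,
                            double alphaMin, double seed) {
  if (vocab < 1 || dim < 1) stop("invalid vocab/dim");
  // corpus frequencies for the noise distribution (unigram^0.75)
  std::vector<double> freq(vocab, 0.0);
  double total = 0.0;
  for (R_xlen_t w = 0; w < walks.size(); ++w) {
    IntegerVector wk = walks[w];
    for (int t = 0; t < wk.size(); ++t) {
      int id = wk[t] - 1;
      if (id < 0 || id >= vocab) stop("walk node id out of range");
      freq[id] += 1.0;
      total += 1.0;
    }
  }
  const int tableSize = 1 << 17;
  std::vector<int> table(tableSize, 0);
  double Z = 0.0;
  for (int i = 0; i < vocab; ++i) Z += std::pow(freq[i], 0.75);
  if (Z <= 0.0) Z = 1.0;
  {
    int i = 0;
    double cum = std::pow(freq[0], 0.75) / Z;
    for (int a = 0; a < tableSize; ++a) {
      table[a] = i;
      if ((a + 1.0) / tableSize > cum && i < vocab - 1) {
        ++i;
        cum += std::pow(freq[i], 0.75) / Z;
      }
    }
  }
  uint64_t st = 0x9E3779B97F4A7C15ULL ^ (uint64_t)(int64_t)seed;
  if (st == 0) st = 1;
  for (int k = 0; k < 8; ++k) xorshift(st);  // warm up

  std::vector<double> syn0((size_t)vocab * dim), syn1((size_t)vocab * dim, 0.0);
  for (size_t k = 0; k < syn0.size(); ++k)
    syn0[k] = (runif01(st) - 0.5) / dim;

  std::vector<double> grad(dim);
  double processed = 0.0, budget = total * std::max(epochs, 1) + 1.0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (R_xlen_t w = 0; w < walks.size(); ++w) {
      IntegerVector wk = walks[w];
      int L = wk.size();
      for (int t = 0; t < L; ++t) {
        processed += 1.0;
        double alpha = alpha0 * (1.0 - processed / budget);
        if (alpha < alphaMin) alpha = alphaMin;
        int center = wk[t] - 1;
        int b = (int)(runif01(st) * window);  // reduced-window subsampling
        for (int c = t - window + b; c <= t + window - b; ++c) {
          if (c == t || c < 0 || c >= L) continue;
          int ctx = wk[c] - 1;
          double *v = &syn0[(size_t)ctx * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int d2 = 0; d2 < negative + 1; ++d2) {
            int target;
            double label;
            if (d2 == 0) {
              target = center;
              label = 1.0;
            } else {
              target = table[(int)(runif01(st) * tableSize)];
              if (target == center) continue;
              label = 0.0;
            }
            double *u = &syn1[(size_t)target * dim];
            double f = 0.0;
            for (int k = 0; k < dim; ++k) f += v[k] * u[k];
            double g;
            if (f > 6.0) g = (label - 1.0) * alpha;
            else if (f < -6.0) g = label * alpha;
            else g = (label - 1.0 / (1.0 + std::exp(-f))) * alpha;
            for (int k = 0; k < dim; ++k) grad[k] += g * u[k];
            for (int k = 0; k < dim; ++k) u[k] += g * v[k];
          }
          for (int k = 0; k < dim; ++k) v[k] += grad[k];
        }
      }
    }
  }
  NumericMatrix out(vocab, dim);
  for (int r = 0; r < vocab; ++r)
    for (int k = 0; k < dim; ++k) out(r, k) = syn0[(size_t)r * dim + k];
  return out;
}
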