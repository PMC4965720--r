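#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Deterministic xorshift64* generator so training never touches R's RNG and
// is bit-for-bit reproducible under the single-worker contract.
struct XorShift64 {
  uint64_t s;
  explicit XorShift64(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12;
    s ^= s << 25;
    s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() {
    // 53-bit mantissa in [0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  int below(int n) { return (int)(unif() * n); }
};

static inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with negative sampling over integer-coded sequences.
// Tokens co-occur when within `window` positions on either side (fixed,
// non-shrinking window). Negatives are drawn from the unigram distribution
// raised to 3/4. Returns the input-layer vectors (vocab x dim).
// [[Rcpp::export]]
NumericMatrix sgns_train(List sequences, int vocab_size, NumericVector counts,
                         int dim, int window, int negatives, int epochs,
                         double alpha, double seed) {
  if (vocab_size <= 0) stop("empty vocabulary");
  XorShift64 rng((uint64_t)seed * 2654435761ULL + 1ULL);

  std::vector<double> syn0((size_t)vocab_size * dim);
  std::vector<double> syn1((size_t)vocab_size * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  // unigram^0.75 table for negative sampling
  const int table_size = 1 << 17;
  std::vector<int> table(table_size);
  double norm = 0.0;
  for (int v = 0; v < vocab_size; ++v) norm += std::pow(counts[v], 0.75);
  {
    int v = 0;
    double cum = std::pow(counts[0], 0.75) / norm;
    for (int t = 0; t < table_size; ++t) {
      table[t] = v;
      if ((t + 1.0) / table_size > cum && v < vocab_size - 1) {
        ++v;
        cum += std::pow(counts[v], 0.75) / norm;
      }
    }
  }

  // pre-extract sequences
  int n_seq = sequences.size();
  std::vector<std::vector<int>> seqs(n_seq);
  long long total_tokens = 0;
  for (int s = 0; s < n_seq; ++s) {
    IntegerVector sq = sequences[s];
    seqs[s].assign(sq.begin(), sq.end());
    total_tokens += sq.size();
  }
  long long train_total = total_tokens * (long long)epochs;
  long long processed = 0;

  std::vector<double> grad(dim);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n_seq; ++s) {
      const std::vector<int>& sq = seqs[s];
      int len = (int)sq.size();
      for (int pos = 0; pos < len; ++pos) {
        double lr = alpha * (1.0 - (double)processed / (train_total + 1));
        if (lr < alpha * 1e-4) lr = alpha * 1e-4;
        ++processed;
        int w = sq[pos];
        int lo = pos - window; if (lo < 0) lo = 0;
        int hi = pos + window; if (hi > len - 1) hi = len - 1;
        for (int cpos = lo; cpos <= hi; ++cpos) {
          if (cpos == pos) continue;
          int c = sq[cpos];
          double* v_w = &syn0[(size_t)w * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int k = 0; k <= negatives; ++k) {
            int target; double label;
            if (k == 0) { target = c; label = 1.0; }
            else {
              target = table[rng.below(table_size)];
              if (target == c) continue;
              label = 0.0;
            }
            double* v_t = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += v_w[d] * v_t[d];
            double g = (label - sigmoid(dot)) * lr;
            for (int d = 0; d < dim; ++d) grad[d] += g * v_t[d];
            for (int d = 0; d < dim; ++d) v_t[d] += g * v_w[d];
          }
          for (int d = 0; d < dim; ++d) v_w[d] += grad[d];
        }
      }
    }
  }

  NumericMatrix out(vocab_size, dim);
  for (int v = 0; v < vocab_size; ++v)
    for (int d = 0; d < dim; ++d)
      out(v, d) = syn0[(size_t)v * dim + d];
  return out;
}
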