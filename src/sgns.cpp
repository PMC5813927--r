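#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

// Skip-gram with negative sampling, single-threaded and fully deterministic
// given the seed. Kept deliberately close to the classic word2vec reference
// behaviour: uniform +/- 0.5/k input init, zero output init, dynamic window
// shrinking, unigram^0.75 negative-sampling distribution, linear learning
// rate decay over the total number of center words processed.

namespace {

// splitmix64: small, deterministic, good-quality PRNG
struct Rng {
  uint64_t state;
  explicit Rng(uint64_t seed) : state(seed + 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

inline double sigmoidd(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

} // namespace

// note_ids: list of integer vectors with 1-based vocabulary indices.
// Returns list(input = vocab x k matrix, output = vocab x k matrix).
// [[Rcpp::export]]
Rcpp::List cpp_sgns_train(Rcpp::List note_ids, int vocab_size, int k,
                          int window, int negatives, int epochs,
                          double lr, int seed) {
  if (k <= 0) Rcpp::stop("embedding dimension k must be > 0");
  if (window <= 0) Rcpp::stop("window must be > 0");
  if (negatives < 1) Rcpp::stop("need at least one negative sample");

  const int n_notes = note_ids.size();
  Rng rng((uint64_t)seed);

  // W_in / W_out as flat row-major buffers
  std::vector<double> w_in((size_t)vocab_size * k);
  std::vector<double> w_out((size_t)vocab_size * k, 0.0);
  for (size_t i = 0; i < w_in.size(); ++i)
    w_in[i] = (rng.unif() - 0.5) / k;

  // unigram counts -> negative-sampling CDF over count^0.75
  std::vector<double> cdf(vocab_size, 0.0);
  {
    std::vector<double> cnt(vocab_size, 0.0);
    long long total_tokens = 0;
    for (int d = 0; d < n_notes; ++d) {
      Rcpp::IntegerVector ids = note_ids[d];
      total_tokens += ids.size();
      for (int t = 0; t < ids.size(); ++t) {
        int id = ids[t] - 1;
        if (id < 0 || id >= vocab_size) Rcpp::stop("token id out of range");
        cnt[id] += 1.0;
      }
    }
    if (total_tokens == 0) Rcpp::stop("corpus is empty");
    double acc = 0.0;
    for (int v = 0; v < vocab_size; ++v) {
      acc += std::pow(cnt[v], 0.75);
      cdf[v] = acc;
    }
    if (acc <= 0.0) Rcpp::stop("no token occurrences");
    for (int v = 0; v < vocab_size; ++v) cdf[v] /= acc;
  }

  auto sample_negative = [&](void) {
    double u = rng.unif();
    int lo = 0, hi = vocab_size - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cdf[mid] < u) lo = mid + 1; else hi = mid;
    }
    return lo;
  };

  long long total_centers = 0;
  for (int d = 0; d < n_notes; ++d)
    total_centers += ((Rcpp::IntegerVector)note_ids[d]).size();
  total_centers *= (long long)epochs;

  const double lr_min = lr * 1e-4;
  long long processed = 0;
  std::vector<double> grad_in(k);

  for (int e = 0; e < epochs; ++e) {
    for (int d = 0; d < n_notes; ++d) {
      Rcpp::IntegerVector ids = note_ids[d];
      const int n = ids.size();
      for (int i = 0; i < n; ++i) {
        double alpha = lr;
        if (total_centers > 0) {
          double frac = (double)processed / (double)total_centers;
          alpha = lr * (1.0 - frac);
          if (alpha < lr_min) alpha = lr_min;
        }
        ++processed;
        int b = 1 + rng.below(window);  // dynamic window
        int center = ids[i] - 1;
        double *vin = &w_in[(size_t)center * k];
        for (int j = i - b; j <= i + b; ++j) {
          if (j < 0 || j >= n || j == i) continue;
          int context = ids[j] - 1;
          for (int c = 0; c < k; ++c) grad_in[c] = 0.0;
          for (int s = 0; s <= negatives; ++s) {
            int target;
            double label;
            if (s == 0) { target = context; label = 1.0; }
            else {
              target = sample_negative();
              if (target == context) continue;
              label = 0.0;
            }
            double *vout = &w_out[(size_t)target * k];
            double dot = 0.0;
            for (int c = 0; c < k; ++c) dot += vin[c] * vout[c];
            double g = (sigmoidd(dot) - label) * alpha;
            for (int c = 0; c < k; ++c) {
              grad_in[c] += g * vout[c];
              vout[c] -= g * vin[c];
            }
          }
          for (int c = 0; c < k; ++c) vin[c] -= grad_in[c];
        }
      }
      if (d % 64 == 0) Rcpp::checkUserInterrupt();
    }
  }

  Rcpp::NumericMatrix min(vocab_size, k), mout(vocab_size, k);
  for (int v = 0; v < vocab_size; ++v)
    for (int c = 0; c < k; ++c) {
      min(v, c) = w_in[(size_t)v * k + c];
      mout(v, c) = w_out[(size_t)v * k + c];
    }
  return Rcpp::List::create(Rcpp::Named("input") = min,
                            Rcpp::Named("output") = mout);
}
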