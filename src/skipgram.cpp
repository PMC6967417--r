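// Skip-gram with negative sampling: single-threaded deterministic SGD.
// Sentences arrive as 0-based vocabulary index vectors; the caller supplies
// the (already normalized) negative-sampling distribution.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// splitmix64: deterministic 64-bit generator, independent of R's RNG so the
// training contract is bit-reproducible across platforms.
static inline uint64_t nextState(uint64_t& s) {
  s += 0x9E3779B97F4A7C15ULL;
  uint64_t z = s;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline double nextUnif(uint64_t& s) {
  return (nextState(s) >> 11) * (1.0 / 9007199254740992.0); // [0, 1)
}

static inline double sigmoidClamped(double x) {
  if (x > 35.0) x = 35.0;
  if (x < -35.0) x = -35.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Draw one negative index from the cumulative distribution, redrawing while
// it collides with the excluded (positive target) index.
static inline int drawNegative(const std::vector<double>& cum, int exclude,
                               uint64_t& s) {
  for (;;) {
    double u = nextUnif(s);
    int idx = (int)(std::upper_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (idx >= (int)cum.size()) idx = (int)cum.size() - 1;
    if (idx != exclude) return idx;
  }
}

// [[Rcpp::export(name = ".sgnsTrain")]]
List sgnsTrain(List sentences, int vocabSize, int dim, int window,
               int negatives, int epochs, double lrStart, double lrEnd,
               NumericVector negProbs, double seed) {
  if (vocabSize < 1) stop("empty vocabulary");
  uint64_t state = (uint64_t)seed * 0x9E3779B97F4A7C15ULL + 1ULL;

  // init: input vectors uniform in (-0.5/dim, 0.5/dim), output vectors zero
  std::vector<double> vin((size_t)vocabSize * dim), vout((size_t)vocabSize * dim, 0.0);
  for (size_t i = 0; i < vin.size(); ++i)
    vin[i] = (nextUnif(state) - 0.5) / dim;

  std::vector<std::vector<int>> sent(sentences.size());
  for (int i = 0; i < sentences.size(); ++i)
    sent[i] = as<std::vector<int>>(sentences[i]);

  std::vector<double> cum(vocabSize);
  double acc = 0.0;
  for (int i = 0; i < vocabSize; ++i) { acc += negProbs[i]; cum[i] = acc; }
  cum[vocabSize - 1] = 1.0 + 1e-12;

  // total scheduled (center, context) pairs, for the linear lr ramp
  long long totalPairs = 0;
  for (const auto& s : sent) {
    long long n = (long long)s.size();
    for (long long i = 0; i < n; ++i) {
      long long lo = std::max(0LL, i - window), hi = std::min(n - 1, i + window);
      totalPairs += hi - lo; // excludes i itself
    }
  }
  totalPairs *= std::max(epochs, 1);

  std::vector<double> neu1e(dim);
  std::vector<int> order(sent.size());
  for (size_t i = 0; i < order.size(); ++i) order[i] = (int)i;

  long long t = 0;
  for (int epoch = 0; epoch < epochs; ++epoch) {
    // Fisher-Yates shuffle of sentence order, driven by the run seed
    for (int i = (int)order.size() - 1; i > 0; --i) {
      int j = (int)(nextUnif(state) * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    for (int si : order) {
      const std::vector<int>& s = sent[si];
      int n = (int)s.size();
      for (int i = 0; i < n; ++i) {
        int center = s[i];
        int lo = std::max(0, i - window), hi = std::min(n - 1, i + window);
        for (int j = lo; j <= hi; ++j) {
          if (j == i) continue;
          double lr = lrStart;
          if (totalPairs > 1)
            lr = lrStart + (lrEnd - lrStart) * ((double)t / (double)(totalPairs - 1));
          ++t;
          int u = s[j];
          double* vc = &vin[(size_t)center * dim];
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int d = 0; d <= negatives; ++d) {
            int target; double label;
            if (d == 0) { target = u; label = 1.0; }
            else { target = drawNegative(cum, u, state); label = 0.0; }
            double* vo = &vout[(size_t)target * dim];
            double dot = 0.0;
            for (int c = 0; c < dim; ++c) dot += vc[c] * vo[c];
            double g = (label - sigmoidClamped(dot)) * lr;
            for (int c = 0; c < dim; ++c) neu1e[c] += g * vo[c];
            for (int c = 0; c < dim; ++c) vo[c] += g * vc[c];
          }
          for (int c = 0; c < dim; ++c) vc[c] += neu1e[c];
        }
      }
    }
  }

  NumericMatrix min(vocabSize, dim), mout(vocabSize, dim);
  for (int i = 0; i < vocabSize; ++i)
    for (int c = 0; c < dim; ++c) {
      min(i, c) = vin[(size_t)i * dim + c];
      mout(i, c) = vout[(size_t)i * dim + c];
    }
  return List::create(_["input"] = min, _["output"] = mout,
                      _["updates"] = (double)t);
}
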