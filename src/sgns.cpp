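#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Skip-gram with negative sampling, single-threaded and driven by a private
// xorshift RNG so training is bit-reproducible for a given seed.

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  uint64_t below(uint64_t n) { return next() % n; }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

} // namespace

// [[Rcpp::export(name = ".sgns_train")]]
NumericMatrix sgns_train(List sentences, int vocab_size, NumericVector counts,
                         int dim, int window, int negative, int epochs,
                         double alpha, double min_alpha, double sample,
                         int seed) {
  if (vocab_size <= 0) stop("empty vocabulary");
  XorShift rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);

  std::vector<double> syn0(static_cast<size_t>(vocab_size) * dim);
  std::vector<double> syn1(static_cast<size_t>(vocab_size) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  // unigram table for negative sampling, counts raised to the 3/4 power
  const int table_size = 1 << 20;
  std::vector<int> table(table_size);
  {
    double total = 0.0;
    for (int v = 0; v < vocab_size; ++v) total += std::pow(counts[v], 0.75);
    double cum = std::pow(counts[0], 0.75) / total;
    int v = 0;
    for (int i = 0; i < table_size; ++i) {
      table[i] = v;
      if ((i + 1.0) / table_size > cum && v < vocab_size - 1) {
        ++v;
        cum += std::pow(counts[v], 0.75) / total;
      }
    }
  }

  double total_tokens = 0.0;
  for (int v = 0; v < vocab_size; ++v) total_tokens += counts[v];

  // total training words for the linear learning-rate decay
  long long corpus_words = 0;
  for (int si = 0; si < sentences.size(); ++si)
    corpus_words += Rf_length(VECTOR_ELT(sentences, si));
  const long long train_total = corpus_words * (long long)epochs + 1;

  std::vector<double> grad(dim);
  long long processed = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int si = 0; si < sentences.size(); ++si) {
      IntegerVector sent = sentences[si];
      // optional frequent-word subsampling
      std::vector<int> kept;
      kept.reserve(sent.size());
      for (int t = 0; t < sent.size(); ++t) {
        int w = sent[t];
        if (sample > 0) {
          double f = counts[w] / total_tokens;
          double keep = (std::sqrt(f / sample) + 1.0) * (sample / f);
          if (keep < rng.unif()) { ++processed; continue; }
        }
        kept.push_back(w);
      }
      const int n = (int)kept.size();
      for (int t = 0; t < n; ++t) {
        ++processed;
        double lr = alpha * (1.0 - (double)processed / train_total);
        if (lr < min_alpha) lr = min_alpha;
        int center = kept[t];
        int b = (int)rng.below((uint64_t)window); // dynamic window shrink
        int lo = t - (window - b); if (lo < 0) lo = 0;
        int hi = t + (window - b); if (hi > n - 1) hi = n - 1;
        for (int c = lo; c <= hi; ++c) {
          if (c == t) continue;
          int context = kept[c];
          double* v_in = &syn0[(size_t)context * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int d = 0; d <= negative; ++d) {
            int target; double label;
            if (d == 0) { target = center; label = 1.0; }
            else {
              target = table[rng.below(table_size)];
              if (target == center) continue;
              label = 0.0;
            }
            double* v_out = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int k = 0; k < dim; ++k) dot += v_in[k] * v_out[k];
            double g = (label - sigmoid(dot)) * lr;
            for (int k = 0; k < dim; ++k) {
              grad[k] += g * v_out[k];
              v_out[k] += g * v_in[k];
            }
          }
          for (int k = 0; k < dim; ++k) v_in[k] += grad[k];
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix out(vocab_size, dim);
  for (int v = 0; v < vocab_size; ++v)
    for (int k = 0; k < dim; ++k)
      out(v, k) = syn0[(size_t)v * dim + k];
  return out;
}
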