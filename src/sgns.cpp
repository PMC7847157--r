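// Skip-gram with negative sampling over a random-walk corpus.
// Single-threaded with an explicit mt19937 seed so training is
// deterministic; desk-scale corpora train in well under a second.
#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

static inline double sigmoid(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// corpus: list of integer vectors of 0-based token ids; vocab size V.
// Returns the V x dim input-embedding matrix.
// [[Rcpp::export]]
NumericMatrix sgns_train(List corpus, int vocab_size, int dim, int window,
                         int epochs, int negative, double alpha, int seed) {
  if (dim <= 0) stop("embedding dimension must be positive");
  if (vocab_size <= 0) stop("empty vocabulary");
  const int V = vocab_size, D = dim;
  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // unigram^0.75 negative-sampling distribution
  std::vector<double> freq(V, 0.0);
  long long total_tokens = 0;
  for (int s = 0; s < corpus.size(); ++s) {
    IntegerVector sent = corpus[s];
    total_tokens += sent.size();
    for (int i = 0; i < sent.size(); ++i) {
      if (sent[i] < 0 || sent[i] >= V) stop("token id out of range");
      freq[sent[i]] += 1.0;
    }
  }
  std::vector<double> cum(V, 0.0);
  double z = 0.0;
  for (int v = 0; v < V; ++v) { z += std::pow(freq[v], 0.75); cum[v] = z; }
  if (z <= 0.0) stop("empty corpus");
  auto sample_negative = [&]() {
    double r = unif(rng) * z;
    int lo = 0, hi = V - 1;
    while (lo < hi) { int mid = (lo + hi) / 2; if (cum[mid] < r) lo = mid + 1; else hi = mid; }
    return lo;
  };

  std::vector<double> syn0((size_t)V * D), syn1((size_t)V * D, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i) syn0[i] = (unif(rng) - 0.5) / D;

  const double min_alpha = alpha * 1e-4;
  long long total_words = (long long)total_tokens * epochs;
  long long words_done = 0;
  std::vector<double> grad(D);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < corpus.size(); ++s) {
      IntegerVector sent = corpus[s];
      int len = sent.size();
      for (int pos = 0; pos < len; ++pos) {
        double lr = alpha * (1.0 - (double)words_done / (double)(total_words + 1));
        if (lr < min_alpha) lr = min_alpha;
        ++words_done;
        int b = (int)(unif(rng) * window);  // dynamic window shrink
        int center = sent[pos];
        double *v_c = &syn0[(size_t)center * D];
        for (int off = b - window; off <= window - b; ++off) {
          if (off == 0) continue;
          int cpos = pos + off;
          if (cpos < 0 || cpos >= len) continue;
          int ctx = sent[cpos];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int k = 0; k <= negative; ++k) {
            int target; double label;
            if (k == 0) { target = ctx; label = 1.0; }
            else {
              target = sample_negative();
              if (target == ctx) continue;
              label = 0.0;
            }
            double *v_t = &syn1[(size_t)target * D];
            double dot = 0.0;
            for (int d = 0; d < D; ++d) dot += v_c[d] * v_t[d];
            double g = (label - sigmoid(dot)) * lr;
            for (int d = 0; d < D; ++d) {
              grad[d] += g * v_t[d];
              v_t[d] += g * v_c[d];
            }
          }
          for (int d = 0; d < D; ++d) v_c[d] += grad[d];
        }
      }
    }
  }

  NumericMatrix out(V, D);
  for (int v = 0; v < V; ++v)
    for (int d = 0; d < D; ++d) out(v, d) = syn0[(size_t)v * D + d];
  return out;
}
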