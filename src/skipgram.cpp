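#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

// Deterministic 64-bit xorshift generator: training must be reproducible from
// the seed alone, independent of R's RNG state and of thread scheduling
// (training is single-threaded by design).
struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  uint64_t below(uint64_t n) { return next() % n; }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// Skip-gram with negative sampling over documents of 0-based token ids.
// counts: per-token corpus frequencies (for the unigram^0.75 negative table).
// Returns the |V| x dim input-vector matrix.
// [[Rcpp::export(name = ".sg_train_cpp")]]
NumericMatrix sg_train_cpp(List docs, NumericVector counts, int dim, int window,
                           int epochs, int negative, double alpha0, int seed) {
  const int V = counts.size();
  XorShift rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);

  std::vector<double> syn0(static_cast<size_t>(V) * dim);
  std::vector<double> syn1(static_cast<size_t>(V) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  // A vocabulary of one word admits no informative (center, context, negative)
  // triples; the initialized vectors are returned untouched.
  if (V >= 2) {
    const int table_size = 100000;
    std::vector<int> table(table_size);
    double z = 0.0;
    for (int v = 0; v < V; ++v) z += std::pow(counts[v], 0.75);
    int v = 0;
    double cum = std::pow(counts[0], 0.75) / z;
    for (int i = 0; i < table_size; ++i) {
      table[i] = v;
      if ((i + 1.0) / table_size > cum && v < V - 1)
        cum += std::pow(counts[++v], 0.75) / z;
    }

    double total = 0.0;
    for (int d = 0; d < docs.size(); ++d)
      total += Rf_length(VECTOR_ELT(docs, d));
    total *= epochs;
    if (total < 1.0) total = 1.0;
    double processed = 0.0;
    const double min_alpha = alpha0 * 1e-4;
    std::vector<double> grad(dim);

    for (int ep = 0; ep < epochs; ++ep) {
      for (int d = 0; d < docs.size(); ++d) {
        IntegerVector doc = docs[d];
        const int n = doc.size();
        for (int pos = 0; pos < n; ++pos, processed += 1.0) {
          double alpha = alpha0 * (1.0 - processed / total);
          if (alpha < min_alpha) alpha = min_alpha;
          const int center = doc[pos];
          // reduced window: effective radius uniform on 1..window
          const int b = 1 + static_cast<int>(rng.below(window));
          for (int off = -b; off <= b; ++off) {
            if (off == 0) continue;
            const int cpos = pos + off;
            if (cpos < 0 || cpos >= n) continue;
            const int context = doc[cpos];
            double *v0 = &syn0[static_cast<size_t>(center) * dim];
            std::fill(grad.begin(), grad.end(), 0.0);
            for (int k = 0; k <= negative; ++k) {
              int target;
              double label;
              if (k == 0) {
                target = context;
                label = 1.0;
              } else {
                target = table[rng.below(table_size)];
                if (target == context) continue;
                label = 0.0;
              }
              double *v1 = &syn1[static_cast<size_t>(target) * dim];
              double f = 0.0;
              for (int j = 0; j < dim; ++j) f += v0[j] * v1[j];
              const double g = (label - sigmoid(f)) * alpha;
              for (int j = 0; j < dim; ++j) grad[j] += g * v1[j];
              for (int j = 0; j < dim; ++j) v1[j] += g * v0[j];
            }
            for (int j = 0; j < dim; ++j) v0[j] += grad[j];
          }
        }
      }
      Rcpp::checkUserInterrupt();
    }
  }

  NumericMatrix out(V, dim);
  for (int w = 0; w < V; ++w)
    for (int j = 0; j < dim; ++j)
      out(w, j) = syn0[static_cast<size_t>(w) * dim + j];
  return out;
}
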