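// Negative-sampling SGD cores for the skip-gram and subword (FastText-style)
// learners. Single-threaded and driven by an internal xorshift RNG so that a
// given seed reproduces the same model bit for bit, independently of R's RNG.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

// splitmix64 to spread the seed, then xorshift64* for the stream
struct Rng {
  uint64_t state;
  explicit Rng(uint64_t seed) {
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    state = z ^ (z >> 31);
    if (state == 0) state = 0x2545F4914F6CDD1DULL;
  }
  uint64_t next() {
    uint64_t x = state;
    x ^= x >> 12;
    x ^= x << 25;
    x ^= x >> 27;
    state = x;
    return x * 0x2545F4914F6CDD1DULL;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  int below(int n) { return static_cast<int>(unif() * n); }
};

inline double sigmoid(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 1e-13;
  return 1.0 / (1.0 + std::exp(-x));
}

// cumulative table for unigram^alpha negative sampling
struct NoiseTable {
  std::vector<double> cum;
  explicit NoiseTable(const NumericVector& probs) {
    cum.resize(probs.size());
    double s = 0.0;
    for (int i = 0; i < probs.size(); ++i) { s += probs[i]; cum[i] = s; }
    for (size_t i = 0; i < cum.size(); ++i) cum[i] /= s;
  }
  int draw(Rng& rng) const {
    double u = rng.unif();
    int lo = 0, hi = static_cast<int>(cum.size()) - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cum[mid] < u) lo = mid + 1; else hi = mid;
    }
    return lo;
  }
};

void shuffle_order(std::vector<int>& order, Rng& rng) {
  for (int i = static_cast<int>(order.size()) - 1; i > 0; --i) {
    int j = rng.below(i + 1);
    std::swap(order[i], order[j]);
  }
}

} // namespace

// Shared SGD loop. When grams_offsets is empty the target side is the plain
// per-token input matrix (skip-gram); otherwise the target vector is the sum
// of the token's n-gram vectors and gradients are distributed over them.
static List run_sgd(const IntegerVector& target,
                    const IntegerVector& context,
                    const NumericVector& noise_probs,
                    const std::vector<int>& grams_flat,
                    const std::vector<int>& grams_off,
                    int n_rows_input, int V, int dim, int epochs,
                    double lr0, double lr_min, int negatives,
                    const NumericVector& pair_weights,
                    uint64_t seed) {
  const bool subword = !grams_off.empty();
  const R_xlen_t n_pairs = target.size();
  Rng rng(seed);
  NoiseTable noise(noise_probs);

  // word2vec-style init: input uniform(-0.5/dim, 0.5/dim), output zero
  std::vector<double> in(static_cast<size_t>(n_rows_input) * dim);
  std::vector<double> out(static_cast<size_t>(V) * dim, 0.0);
  for (size_t i = 0; i < in.size(); ++i) {
    in[i] = (rng.unif() - 0.5) / dim;
  }

  std::vector<int> order(n_pairs);
  for (R_xlen_t i = 0; i < n_pairs; ++i) order[i] = static_cast<int>(i);

  std::vector<double> h(dim), grad(dim);
  NumericVector epoch_loss(epochs);
  const double total_updates = static_cast<double>(epochs) * n_pairs;
  double done = 0.0;

  for (int ep = 0; ep < epochs; ++ep) {
    shuffle_order(order, rng);
    double loss_sum = 0.0;
    for (R_xlen_t p = 0; p < n_pairs; ++p) {
      const int idx = order[p];
      const int t = target[idx];
      const int c = context[idx];
      double lr = lr0 + (lr_min - lr0) * (done / total_updates);
      done += 1.0;
      if (pair_weights.size() > 0) lr *= pair_weights[idx];

      // target-side hidden vector
      const int* g_begin = nullptr;
      int n_g = 0;
      if (subword) {
        g_begin = grams_flat.data() + grams_off[t];
        n_g = grams_off[t + 1] - grams_off[t];
        std::fill(h.begin(), h.end(), 0.0);
        for (int gi = 0; gi < n_g; ++gi) {
          const double* z = &in[static_cast<size_t>(g_begin[gi]) * dim];
          for (int d = 0; d < dim; ++d) h[d] += z[d];
        }
      } else {
        const double* vt = &in[static_cast<size_t>(t) * dim];
        std::copy(vt, vt + dim, h.begin());
      }

      std::fill(grad.begin(), grad.end(), 0.0);
      for (int s = 0; s <= negatives; ++s) {
        int o;
        double label;
        if (s == 0) { o = c; label = 1.0; }
        else {
          o = noise.draw(rng);
          if (o == c) continue; // skip accidental positives
          label = 0.0;
        }
        double* vo = &out[static_cast<size_t>(o) * dim];
        double dot = 0.0;
        for (int d = 0; d < dim; ++d) dot += h[d] * vo[d];
        double f = sigmoid(dot);
        loss_sum += (label == 1.0) ? -std::log(std::max(f, 1e-13))
                                   : -std::log(std::max(1.0 - f, 1e-13));
        double g = (label - f) * lr;
        for (int d = 0; d < dim; ++d) {
          grad[d] += g * vo[d];
          vo[d] += g * h[d];
        }
      }

      if (subword) {
        for (int gi = 0; gi < n_g; ++gi) {
          double* z = &in[static_cast<size_t>(g_begin[gi]) * dim];
          for (int d = 0; d < dim; ++d) z[d] += grad[d];
        }
      } else {
        double* vt = &in[static_cast<size_t>(t) * dim];
        for (int d = 0; d < dim; ++d) vt[d] += grad[d];
      }
    }
    epoch_loss[ep] = loss_sum / n_pairs;
  }

  NumericMatrix input(n_rows_input, dim), output(V, dim);
  for (int i = 0; i < n_rows_input; ++i)
    for (int d = 0; d < dim; ++d)
      input(i, d) = in[static_cast<size_t>(i) * dim + d];
  for (int i = 0; i < V; ++i)
    for (int d = 0; d < dim; ++d)
      output(i, d) = out[static_cast<size_t>(i) * dim + d];
  return List::create(_["input"] = input, _["output"] = output,
                      _["epoch_loss"] = epoch_loss);
}

// [[Rcpp::export]]
List sgns_train_cpp(IntegerVector target, IntegerVector context,
                    NumericVector noise_probs, int V, int dim, int epochs,
                    double lr0, double lr_min, int negatives,
                    NumericVector pair_weights, double seed) {
  return run_sgd(target, context, noise_probs, std::vector<int>(),
                 std::vector<int>(), V, V, dim, epochs, lr0, lr_min,
                 negatives, pair_weights, static_cast<uint64_t>(seed));
}

// [[Rcpp::export]]
List fasttext_train_cpp(IntegerVector target, IntegerVector context,
                        NumericVector noise_probs,
                        IntegerVector grams_flat, IntegerVector grams_offsets,
                        int n_grams, int V, int dim, int epochs,
                        double lr0, double lr_min, int negatives,
                        NumericVector pair_weights, double seed) {
  std::vector<int> flat(grams_flat.begin(), grams_flat.end());
  std::vector<int> off(grams_offsets.begin(), grams_offsets.end());
  return run_sgd(target, context, noise_probs, flat, off,
                 n_grams, V, dim, epochs, lr0, lr_min, negatives,
                 pair_weights, static_cast<uint64_t>(seed));
}
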