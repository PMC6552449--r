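#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

// Compact reference trainers for CBOW / skip-gram negative sampling (with
// optional subword units, fastText-style) and AdaGrad GloVe. Single-threaded
// and fully deterministic given the seed: randomness comes from an internal
// splitmix64 generator, never from the standard library's distributions,
// whose output is implementation-defined.

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed + 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s += 0x9E3779B97F4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// unigram^0.75 negative-sampling table
std::vector<int> build_unigram_table(const IntegerVector& counts, int table_size) {
  int v = counts.size();
  std::vector<int> table(table_size);
  double total = 0.0;
  for (int i = 0; i < v; ++i) total += std::pow((double)counts[i], 0.75);
  double cum = std::pow((double)counts[0], 0.75) / total;
  int w = 0;
  for (int t = 0; t < table_size; ++t) {
    table[t] = w;
    if ((double)(t + 1) / table_size > cum && w < v - 1) {
      ++w;
      cum += std::pow((double)counts[w], 0.75) / total;
    }
  }
  return table;
}

}  // namespace

// Train CBOW or skip-gram vectors with negative sampling.
// sentences: list of 0-based integer id vectors. subwords: per-word integer
// vector of 0-based bucket ids (length-0 list disables subword units).
// Returns the v x dim matrix of input vectors (word + mean of its subword
// vectors when subwords are used, matching the training-time representation).
// [[Rcpp::export]]
NumericMatrix cpp_train_w2v(List sentences, IntegerVector counts, int dim,
                            int window, int epochs, int negative, double alpha,
                            int seed, bool cbow, List subwords, int n_buckets) {
  const int v = counts.size();
  const bool use_sub = subwords.size() > 0;
  const int n_in = v + (use_sub ? n_buckets : 0);

  Rng rng(static_cast<uint64_t>(seed));
  std::vector<double> syn0((size_t)n_in * dim);
  std::vector<double> syn1((size_t)v * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  std::vector<int> table = build_unigram_table(counts, 100000);

  // pre-extract sentences and subword lists
  std::vector<std::vector<int>> sent;
  sent.reserve(sentences.size());
  long long total_words = 0;
  for (int i = 0; i < sentences.size(); ++i) {
    IntegerVector s = sentences[i];
    sent.emplace_back(s.begin(), s.end());
    total_words += s.size();
  }
  std::vector<std::vector<int>> sub(v);
  if (use_sub) {
    for (int w = 0; w < v; ++w) {
      IntegerVector g = subwords[w];
      sub[w].assign(g.begin(), g.end());
    }
  }

  const double min_alpha_frac = 1e-4;
  long long processed = 0;
  const long long grand_total = total_words * (long long)epochs;
  std::vector<double> h(dim), neu1e(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (size_t si = 0; si < sent.size(); ++si) {
      const std::vector<int>& words = sent[si];
      const int n = (int)words.size();
      for (int pos = 0; pos < n; ++pos) {
        ++processed;
        double lr = alpha * std::max(1.0 - (double)processed / (grand_total + 1.0),
                                     min_alpha_frac);
        const int center = words[pos];
        const int b = rng.below(window);  // dynamic window shrink
        const int lo = std::max(0, pos - window + b);
        const int hi = std::min(n - 1, pos + window - b);

        if (cbow) {
          // h = mean representation of context words; predict center
          std::fill(h.begin(), h.end(), 0.0);
          int cw = 0;
          for (int p = lo; p <= hi; ++p) {
            if (p == pos) continue;
            const int wo = words[p];
            const double* r = &syn0[(size_t)wo * dim];
            const int parts = 1 + (use_sub ? (int)sub[wo].size() : 0);
            for (int d = 0; d < dim; ++d) h[d] += r[d] / parts;
            if (use_sub)
              for (int g : sub[wo]) {
                const double* gr = &syn0[(size_t)(v + g) * dim];
                for (int d = 0; d < dim; ++d) h[d] += gr[d] / parts;
              }
            ++cw;
          }
          if (cw == 0) continue;
          for (int d = 0; d < dim; ++d) h[d] /= cw;
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int k = 0; k <= negative; ++k) {
            int target;
            double label;
            if (k == 0) { target = center; label = 1.0; }
            else {
              target = table[rng.below((int)table.size())];
              if (target == center) continue;
              label = 0.0;
            }
            double* out = &syn1[(size_t)target * dim];
            double f = 0.0;
            for (int d = 0; d < dim; ++d) f += h[d] * out[d];
            const double g = (label - sigmoid(f)) * lr;
            for (int d = 0; d < dim; ++d) neu1e[d] += g * out[d];
            for (int d = 0; d < dim; ++d) out[d] += g * h[d];
          }
          for (int p = lo; p <= hi; ++p) {
            if (p == pos) continue;
            const int wo = words[p];
            const int parts = 1 + (use_sub ? (int)sub[wo].size() : 0);
            double* r = &syn0[(size_t)wo * dim];
            for (int d = 0; d < dim; ++d) r[d] += neu1e[d] / parts;
            if (use_sub)
              for (int g : sub[wo]) {
                double* gr = &syn0[(size_t)(v + g) * dim];
                for (int d = 0; d < dim; ++d) gr[d] += neu1e[d] / parts;
              }
          }
        } else {
          // skip-gram: representation of the center predicts each context word
          const std::vector<int>* csub = use_sub ? &sub[center] : nullptr;
          const int parts = 1 + (use_sub ? (int)csub->size() : 0);
          std::fill(h.begin(), h.end(), 0.0);
          {
            const double* r = &syn0[(size_t)center * dim];
            for (int d = 0; d < dim; ++d) h[d] += r[d];
            if (use_sub)
              for (int g : *csub) {
                const double* gr = &syn0[(size_t)(v + g) * dim];
                for (int d = 0; d < dim; ++d) h[d] += gr[d];
              }
            for (int d = 0; d < dim; ++d) h[d] /= parts;
          }
          for (int p = lo; p <= hi; ++p) {
            if (p == pos) continue;
            const int ctx = words[p];
            std::fill(neu1e.begin(), neu1e.end(), 0.0);
            for (int k = 0; k <= negative; ++k) {
              int target;
              double label;
              if (k == 0) { target = ctx; label = 1.0; }
              else {
                target = table[rng.below((int)table.size())];
                if (target == ctx) continue;
                label = 0.0;
              }
              double* out = &syn1[(size_t)target * dim];
              double f = 0.0;
              for (int d = 0; d < dim; ++d) f += h[d] * out[d];
              const double g = (label - sigmoid(f)) * lr;
              for (int d = 0; d < dim; ++d) neu1e[d] += g * out[d];
              for (int d = 0; d < dim; ++d) out[d] += g * h[d];
            }
            double* r = &syn0[(size_t)center * dim];
            for (int d = 0; d < dim; ++d) {
              const double upd = neu1e[d] / parts;
              r[d] += upd;
              h[d] += upd;  // keep h in sync with the updated representation
            }
            if (use_sub)
              for (int g : *csub) {
                double* gr = &syn0[(size_t)(v + g) * dim];
                for (int d = 0; d < dim; ++d) gr[d] += neu1e[d] / parts;
              }
          }
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix out(v, dim);
  for (int w = 0; w < v; ++w) {
    const double* r = &syn0[(size_t)w * dim];
    if (!use_sub) {
      for (int d = 0; d < dim; ++d) out(w, d) = r[d];
    } else {
      const int parts = 1 + (int)sub[w].size();
      for (int d = 0; d < dim; ++d) out(w, d) = r[d] / parts;
      for (int g : sub[w]) {
        const double* gr = &syn0[(size_t)(v + g) * dim];
        for (int d = 0; d < dim; ++d) out(w, d) += gr[d] / parts;
      }
    }
  }
  return out;
}

// GloVe: weighted least squares on log co-occurrence counts, AdaGrad updates.
// Returns W + W~ (sum of word and context vectors), the usual reported form.
// [[Rcpp::export]]
NumericMatrix cpp_train_glove(List sentences, int vocab_size, int dim,
                              int window, int epochs, double alpha,
                              double x_max, int seed) {
  // harvest co-occurrence with 1/distance weighting, symmetric window
  std::unordered_map<uint64_t, double> cooc;
  for (int i = 0; i < sentences.size(); ++i) {
    IntegerVector s = sentences[i];
    const int n = s.size();
    for (int pos = 0; pos < n; ++pos) {
      for (int off = 1; off <= window && pos + off < n; ++off) {
        const uint64_t a = s[pos], b = s[pos + off];
        const double w = 1.0 / off;
        cooc[a * (uint64_t)vocab_size + b] += w;
        cooc[b * (uint64_t)vocab_size + a] += w;
      }
    }
  }
  std::vector<uint64_t> keys;
  keys.reserve(cooc.size());
  for (auto& kv : cooc) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());  // hash order is not reproducible

  Rng rng(static_cast<uint64_t>(seed));
  const size_t vd = (size_t)vocab_size * dim;
  std::vector<double> W(vd), Wt(vd), b(vocab_size), bt(vocab_size);
  std::vector<double> gW(vd, 1.0), gWt(vd, 1.0), gb(vocab_size, 1.0),
      gbt(vocab_size, 1.0);
  for (size_t i = 0; i < vd; ++i) W[i] = (rng.unif() - 0.5) / dim;
  for (size_t i = 0; i < vd; ++i) Wt[i] = (rng.unif() - 0.5) / dim;
  for (int i = 0; i < vocab_size; ++i) b[i] = (rng.unif() - 0.5) / dim;
  for (int i = 0; i < vocab_size; ++i) bt[i] = (rng.unif() - 0.5) / dim;

  std::vector<size_t> order(keys.size());
  for (size_t i = 0; i < order.size(); ++i) order[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle of the triplet order
    for (size_t i = order.size(); i > 1; --i) {
      size_t j = (size_t)rng.below((int)i);
      std::swap(order[i - 1], order[j]);
    }
    for (size_t oi = 0; oi < order.size(); ++oi) {
      const uint64_t key = keys[order[oi]];
      const int wi = (int)(key / vocab_size), wj = (int)(key % vocab_size);
      const double x = cooc[key];
      const double fx = x < x_max ? std::pow(x / x_max, 0.75) : 1.0;
      double* vi = &W[(size_t)wi * dim];
      double* vj = &Wt[(size_t)wj * dim];
      double dot = b[wi] + bt[wj] - std::log(x);
      for (int d = 0; d < dim; ++d) dot += vi[d] * vj[d];
      const double fdiff = fx * dot;
      for (int d = 0; d < dim; ++d) {
        const double gi = fdiff * vj[d], gj = fdiff * vi[d];
        const size_t ii = (size_t)wi * dim + d, jj = (size_t)wj * dim + d;
        W[ii] -= alpha * gi / std::sqrt(gW[ii]);
        Wt[jj] -= alpha * gj / std::sqrt(gWt[jj]);
        gW[ii] += gi * gi;
        gWt[jj] += gj * gj;
      }
      b[wi] -= alpha * fdiff / std::sqrt(gb[wi]);
      bt[wj] -= alpha * fdiff / std::sqrt(gbt[wj]);
      gb[wi] += fdiff * fdiff;
      gbt[wj] += fdiff * fdiff;
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix out(vocab_size, dim);
  for (int w = 0; w < vocab_size; ++w)
    for (int d = 0; d < dim; ++d)
      out(w, d) = W[(size_t)w * dim + d] + Wt[(size_t)w * dim + d];
  return out;
}
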