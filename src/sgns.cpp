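#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

// Skip-gram word embeddings with negative sampling (SGNS), plain SGD.
//
// docs: list of integer vectors with 0-based word ids. Single-threaded with
// a private std::mt19937 so a fixed seed gives identical vectors. Negative
// samples are drawn from the unigram distribution raised to 0.75, the usual
// choice. The learning rate decays linearly over all (epoch, token) steps.
// Weights are single-precision with a tabulated sigmoid, as in the original
// word2vec implementation. Returns the input-side embedding matrix (V x dim).

static const int EXP_TABLE_SIZE = 1000;
static const float MAX_EXP = 6.0f;

// [[Rcpp::export]]
NumericMatrix sgns_train(const List& docs, int V, int dim, int window,
                         int negative, int epochs, double lr, int seed) {
  const int D = docs.size();
  std::vector<std::vector<int>> dd(D);
  std::vector<double> freq(V, 0.0);
  long long n_tokens = 0;
  for (int i = 0; i < D; ++i) {
    IntegerVector di = docs[i];
    dd[i].assign(di.begin(), di.end());
    for (int id : dd[i]) freq[id] += 1.0;
    n_tokens += di.size();
  }

  std::vector<float> sig(EXP_TABLE_SIZE);
  for (int i = 0; i < EXP_TABLE_SIZE; ++i) {
    float x = (i / (float)EXP_TABLE_SIZE * 2.0f - 1.0f) * MAX_EXP;
    sig[i] = 1.0f / (1.0f + std::exp(-x));
  }

  // cumulative table for unigram^0.75 negative sampling
  std::vector<double> cum(V);
  double s = 0.0;
  for (int v = 0; v < V; ++v) {
    s += std::pow(freq[v], 0.75);
    cum[v] = s;
  }

  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  auto draw_neg = [&]() {
    double u = unif(rng) * s;
    int lo = 0, hi = V - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cum[mid] < u) lo = mid + 1; else hi = mid;
    }
    return lo;
  };

  std::vector<float> win(static_cast<size_t>(V) * dim);
  std::vector<float> wout(static_cast<size_t>(V) * dim, 0.0f);
  for (auto& x : win) x = (static_cast<float>(unif(rng)) - 0.5f) / dim;

  const double total_steps = static_cast<double>(epochs) * n_tokens;
  long long step = 0;
  std::vector<float> err(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int di = 0; di < D; ++di) {
      const std::vector<int>& doc = dd[di];
      const int n = static_cast<int>(doc.size());
      for (int i = 0; i < n; ++i, ++step) {
        float a = static_cast<float>(lr * std::max(1e-4,
                                                   1.0 - step / total_steps));
        // dynamic window, as in the reference implementation
        int b = 1 + static_cast<int>(unif(rng) * window);
        int center = doc[i];
        float* vin = &win[static_cast<size_t>(center) * dim];
        for (int j = i - b; j <= i + b; ++j) {
          if (j < 0 || j >= n || j == i) continue;
          int ctx = doc[j];
          std::fill(err.begin(), err.end(), 0.0f);
          for (int k = 0; k <= negative; ++k) {
            int target;
            float label;
            if (k == 0) {
              target = ctx;
              label = 1.0f;
            } else {
              target = draw_neg();
              if (target == ctx) continue;
              label = 0.0f;
            }
            float* vo = &wout[static_cast<size_t>(target) * dim];
            float dot = 0.0f;
            for (int c = 0; c < dim; ++c) dot += vin[c] * vo[c];
            float f;
            if (dot > MAX_EXP) f = 1.0f;
            else if (dot < -MAX_EXP) f = 0.0f;
            else f = sig[(int)((dot + MAX_EXP) *
                               (EXP_TABLE_SIZE / MAX_EXP / 2.0f))];
            float g = (label - f) * a;
            for (int c = 0; c < dim; ++c) {
              err[c] += g * vo[c];
              vo[c] += g * vin[c];
            }
          }
          for (int c = 0; c < dim; ++c) vin[c] += err[c];
        }
      }
    }
  }

  NumericMatrix out(V, dim);
  for (int v = 0; v < V; ++v)
    for (int c = 0; c < dim; ++c)
      out(v, c) = win[static_cast<size_t>(v) * dim + c];
  return out;
}
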