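#include <Rcpp.h>
#include <random>
#include <vector>
using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation.
//
// docs: list of integer vectors, 0-based word ids into a vocabulary of size V.
// Uses its own std::mt19937 so results depend only on `seed` (never on R's
// RNG state) and are reproducible run-to-run on the same platform.
//
// Returns the final count tables; the smoothed phi/theta estimates are
// assembled on the R side.
// [[Rcpp::export]]
List lda_gibbs_fit(const List& docs, int V, int K, double alpha, double beta,
                   int iterations, int seed) {
  const int D = docs.size();
  std::vector<int> w, d;
  for (int i = 0; i < D; ++i) {
    IntegerVector di = docs[i];
    for (int j = 0; j < di.size(); ++j) {
      w.push_back(di[j]);
      d.push_back(i);
    }
  }
  const int N = static_cast<int>(w.size());

  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  IntegerMatrix ndk(D, K);  // doc x topic counts
  IntegerMatrix nkw(K, V);  // topic x word counts
  std::vector<int> nk(K, 0), z(N);

  for (int i = 0; i < N; ++i) {
    int t = std::min(K - 1, static_cast<int>(unif(rng) * K));
    z[i] = t;
    ndk(d[i], t)++;
    nkw(t, w[i])++;
    nk[t]++;
  }

  std::vector<double> p(K);
  const double Vb = V * beta;
  for (int it = 0; it < iterations; ++it) {
    for (int i = 0; i < N; ++i) {
      const int di_ = d[i], wi = w[i];
      int zi = z[i];
      ndk(di_, zi)--;
      nkw(zi, wi)--;
      nk[zi]--;
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        p[k] = (ndk(di_, k) + alpha) * (nkw(k, wi) + beta) / (nk[k] + Vb);
        tot += p[k];
      }
      double u = unif(rng) * tot, cum = 0.0;
      int t = K - 1;
      for (int k = 0; k < K; ++k) {
        cum += p[k];
        if (u < cum) { t = k; break; }
      }
      z[i] = t;
      ndk(di_, t)++;
      nkw(t, wi)++;
      nk[t]++;
    }
  }

  return List::create(_["ndk"] = ndk, _["nkw"] = nkw,
                      _["nk"] = IntegerVector(nk.begin(), nk.end()),
                      _["n_tokens"] = N);
}
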