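#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation, with an optional
// tempering exponent on the word likelihood so the same kernel serves both
// ordinary posterior sampling (temper = 1) and the power-posterior rungs of
// thermodynamic integration (0 <= temper < 1), where the target is
// p(z) * p(w | z)^temper.
//
// Token conditional (token removed from counts):
//   p(z = k | .) propto (n_dk + alpha) * [(n_kv + beta) / (n_k + V beta)]^t
// The powered terms depend only on integer counts, so (c + beta)^t and
// (c + V beta)^t are precomputed as lookup tables over c = 0..N; the inner
// loop then costs the same as the untempered sampler.
//
// RNG: R's generator via unif_rand(), so set.seed() on the R side gives
// byte-identical chains. Sweep order is doc-major, token-minor (the order of
// the token stream passed in).

static inline int sample_index(const std::vector<double> &w, int K) {
  double tot = 0.0;
  for (int k = 0; k < K; ++k) tot += w[k];
  double u = unif_rand() * tot;
  double acc = 0.0;
  for (int k = 0; k < K; ++k) {
    acc += w[k];
    if (u <= acc) return k;
  }
  return K - 1;
}

// [[Rcpp::export(name = ".lda_gibbs_cpp")]]
List lda_gibbs_cpp(IntegerVector word, IntegerVector doc,
                   int D, int V, int K,
                   double alpha, double beta,
                   int n_iter, int burnin,
                   double temper,
                   IntegerVector z_init,
                   bool accumulate_mean,
                   bool record_z,
                   bool record_logjoint) {
  const int N = word.size();
  if (doc.size() != N) stop("word/doc length mismatch");
  if (N == 0) stop("empty token stream");

  std::vector<int> z(N);
  std::vector<int> ndk((size_t)D * K, 0), nkv((size_t)V * K, 0);
  std::vector<int> nk(K, 0), nd(D, 0);

  bool have_init = z_init.size() == N;
  for (int i = 0; i < N; ++i) {
    int zi = have_init ? z_init[i] : (int)std::floor(unif_rand() * K);
    if (zi < 0 || zi >= K) zi = 0;
    z[i] = zi;
    ndk[(size_t)doc[i] * K + zi]++;
    nkv[(size_t)word[i] * K + zi]++;
    nk[zi]++;
    nd[doc[i]]++;
  }

  // count-indexed lookup tables (counts never exceed N); powB holds the
  // reciprocal so the inner loop multiplies instead of divides
  std::vector<double> powA(N + 1), powB(N + 1);   // (c+beta)^t, (c+V beta)^-t
  std::vector<double> lgA(N + 1), lgB(N + 1);     // lgamma(c+beta), lgamma(c+V beta)
  std::vector<double> lgAd(N + 1), lgBd(N + 1);   // lgamma(c+alpha), lgamma(c+K alpha)
  for (int c = 0; c <= N; ++c) {
    powA[c] = std::pow((double)c + beta, temper);
    powB[c] = std::pow((double)c + V * beta, -temper);
    lgA[c]  = std::lgamma((double)c + beta);
    lgB[c]  = std::lgamma((double)c + V * beta);
    lgAd[c] = std::lgamma((double)c + alpha);
    lgBd[c] = std::lgamma((double)c + K * alpha);
  }
  const double lgA0 = lgA[0], lgB0 = lgB[0], lgAd0 = lgAd[0], lgBd0 = lgBd[0];

  NumericVector logpw_trace(n_iter);
  NumericVector logjoint_trace(record_logjoint ? n_iter : 0);
  IntegerMatrix z_trace(record_z ? n_iter : 0, record_z ? N : 0);

  std::vector<double> theta_acc, phi_acc;
  int n_acc = 0;
  if (accumulate_mean) {
    theta_acc.assign((size_t)D * K, 0.0);
    phi_acc.assign((size_t)V * K, 0.0);
  }

  std::vector<double> wgt(K);

  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < N; ++i) {
      const int d = doc[i], v = word[i], old = z[i];
      int *ndk_d = &ndk[(size_t)d * K];
      int *nkv_v = &nkv[(size_t)v * K];
      ndk_d[old]--; nkv_v[old]--; nk[old]--;
      for (int k = 0; k < K; ++k)
        wgt[k] = (ndk_d[k] + alpha) * powA[nkv_v[k]] * powB[nk[k]];
      const int knew = sample_index(wgt, K);
      z[i] = knew;
      ndk_d[knew]++; nkv_v[knew]++; nk[knew]++;
    }

    // log p(w | z) from current counts
    double lpw = 0.0;
    for (int k = 0; k < K; ++k) {
      lpw += lgB0 - lgB[nk[k]];
      for (int v = 0; v < V; ++v) {
        const int c = nkv[(size_t)v * K + k];
        if (c > 0) lpw += lgA[c] - lgA0;
      }
    }
    logpw_trace[it] = lpw;

    if (record_logjoint) {
      double lpz = 0.0;
      for (int d = 0; d < D; ++d) {
        lpz += lgBd0 - lgBd[nd[d]];
        for (int k = 0; k < K; ++k) {
          const int c = ndk[(size_t)d * K + k];
          if (c > 0) lpz += lgAd[c] - lgAd0;
        }
      }
      logjoint_trace[it] = lpz + lpw;
    }

    if (record_z)
      for (int i = 0; i < N; ++i) z_trace(it, i) = z[i];

    if (accumulate_mean && it >= burnin) {
      n_acc++;
      for (int d = 0; d < D; ++d) {
        const double den = nd[d] + K * alpha;
        for (int k = 0; k < K; ++k)
          theta_acc[(size_t)d * K + k] += (ndk[(size_t)d * K + k] + alpha) / den;
      }
      for (int k = 0; k < K; ++k) {
        const double den = nk[k] + V * beta;
        for (int v = 0; v < V; ++v)
          phi_acc[(size_t)v * K + k] += (nkv[(size_t)v * K + k] + beta) / den;
      }
    }

    if (it % 64 == 0) Rcpp::checkUserInterrupt();
  }

  // final-state (last-sample) estimates
  NumericMatrix theta_last(D, K), phi_last(K, V);
  for (int d = 0; d < D; ++d) {
    const double den = nd[d] + K * alpha;
    for (int k = 0; k < K; ++k)
      theta_last(d, k) = (ndk[(size_t)d * K + k] + alpha) / den;
  }
  for (int k = 0; k < K; ++k) {
    const double den = nk[k] + V * beta;
    for (int v = 0; v < V; ++v)
      phi_last(k, v) = (nkv[(size_t)v * K + k] + beta) / den;
  }

  List out = List::create(
    _["z"] = IntegerVector(z.begin(), z.end()),
    _["logpw_trace"] = logpw_trace,
    _["theta_last"] = theta_last,
    _["phi_last"] = phi_last,
    _["n_acc"] = n_acc);
  if (accumulate_mean && n_acc > 0) {
    NumericMatrix theta_mean(D, K), phi_mean(K, V);
    for (int d = 0; d < D; ++d)
      for (int k = 0; k < K; ++k)
        theta_mean(d, k) = theta_acc[(size_t)d * K + k] / n_acc;
    for (int k = 0; k < K; ++k)
      for (int v = 0; v < V; ++v)
        phi_mean(k, v) = phi_acc[(size_t)v * K + k] / n_acc;
    out["theta_mean"] = theta_mean;
    out["phi_mean"] = phi_mean;
  }
  if (record_logjoint) out["logjoint_trace"] = logjoint_trace;
  if (record_z) out["z_trace"] = z_trace;
  return out;
}
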