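#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for LDA over presence/absence tokens.
// doc/word are 0-based token indices; uses R's RNG so set.seed() governs
// reproducibility. Point estimates are averaged over post-burn-in samples
// taken every `sample_lag` sweeps; the log joint p(w, z) is recorded per
// sweep.
// [[Rcpp::export]]
List lda_gibbs_cpp(IntegerVector doc, IntegerVector word,
                   int n_docs, int n_words, int K,
                   int n_iter, double alpha, double beta,
                   int burn_in, int sample_lag) {
  const int n_tokens = doc.size();
  IntegerVector z(n_tokens);
  IntegerMatrix n_dk(n_docs, K), n_kw(K, n_words);
  IntegerVector n_k(K), n_d(n_docs);

  RNGScope scope;

  for (int t = 0; t < n_tokens; ++t) {
    int k = (int)(unif_rand() * K);
    if (k == K) k = K - 1;
    z[t] = k;
    n_dk(doc[t], k)++; n_kw(k, word[t])++; n_k[k]++; n_d[doc[t]]++;
  }

  NumericVector p(K), loglik(n_iter);
  NumericMatrix theta_acc(n_docs, K), phi_acc(K, n_words);
  int n_samples = 0;
  const double Vbeta = n_words * beta;

  for (int iter = 0; iter < n_iter; ++iter) {
    for (int t = 0; t < n_tokens; ++t) {
      const int d = doc[t], w = word[t];
      int k = z[t];
      n_dk(d, k)--; n_kw(k, w)--; n_k[k]--;
      double tot = 0.0;
      for (int j = 0; j < K; ++j) {
        p[j] = (n_dk(d, j) + alpha) * (n_kw(j, w) + beta) / (n_k[j] + Vbeta);
        tot += p[j];
      }
      double u = unif_rand() * tot, cum = 0.0;
      k = K - 1;
      for (int j = 0; j < K; ++j) {
        cum += p[j];
        if (u <= cum) { k = j; break; }
      }
      z[t] = k;
      n_dk(d, k)++; n_kw(k, w)++; n_k[k]++;
    }

    // log p(w | z) + log p(z)
    double ll = K * (R::lgammafn(Vbeta) - n_words * R::lgammafn(beta));
    for (int k = 0; k < K; ++k) {
      for (int w = 0; w < n_words; ++w)
        if (n_kw(k, w) > 0) ll += R::lgammafn(n_kw(k, w) + beta) - R::lgammafn(beta);
      ll -= R::lgammafn(n_k[k] + Vbeta) - R::lgammafn(Vbeta);
    }
    ll += n_docs * (R::lgammafn(K * alpha) - K * R::lgammafn(alpha));
    for (int d = 0; d < n_docs; ++d) {
      for (int k = 0; k < K; ++k)
        if (n_dk(d, k) > 0) ll += R::lgammafn(n_dk(d, k) + alpha) - R::lgammafn(alpha);
      ll -= R::lgammafn(n_d[d] + K * alpha) - R::lgammafn(K * alpha);
    }
    loglik[iter] = ll;

    if (iter >= burn_in && ((iter - burn_in) % sample_lag == 0)) {
      for (int d = 0; d < n_docs; ++d)
        for (int k = 0; k < K; ++k)
          theta_acc(d, k) += (n_dk(d, k) + alpha) / (n_d[d] + K * alpha);
      for (int k = 0; k < K; ++k)
        for (int w = 0; w < n_words; ++w)
          phi_acc(k, w) += (n_kw(k, w) + beta) / (n_k[k] + Vbeta);
      n_samples++;
    }
  }

  if (n_samples > 0) {
    theta_acc = theta_acc / n_samples;
    phi_acc = phi_acc / n_samples;
  }
  return List::create(_["cell_topic"] = theta_acc, _["topic_region"] = phi_acc,
                      _["loglik"] = loglik, _["n_samples"] = n_samples,
                      _["token_total"] = n_tokens);
}
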