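#include <Rcpp.h>
using namespace Rcpp;

// Log-space inference for a linear-chain CRF with K states.
// E holds per-position log emission scores for all sequences stacked
// row-wise; lens gives the length of each sequence. Tw is the K x K
// matrix of transition log-potentials (state at i -> state at i+1).

static inline double log_sum_exp(const double *v, int k) {
  double m = v[0];
  for (int i = 1; i < k; ++i) if (v[i] > m) m = v[i];
  if (!R_finite(m)) return m;
  double s = 0.0;
  for (int i = 0; i < k; ++i) s += std::exp(v[i] - m);
  return m + std::log(s);
}

// [[Rcpp::export]]
List crf_forward_backward(NumericMatrix E, NumericMatrix Tw, IntegerVector lens) {
  const int K = E.ncol();
  const int nseq = lens.size();
  NumericMatrix marg(E.nrow(), K);
  NumericMatrix trans_exp(K, K);
  NumericVector logZ(nseq);
  std::vector<double> buf(K);

  int off = 0;
  for (int s = 0; s < nseq; ++s) {
    const int L = lens[s];
    NumericMatrix alpha(L, K), beta(L, K);
    for (int k = 0; k < K; ++k) alpha(0, k) = E(off, k);
    for (int i = 1; i < L; ++i)
      for (int k = 0; k < K; ++k) {
        for (int j = 0; j < K; ++j) buf[j] = alpha(i - 1, j) + Tw(j, k);
        alpha(i, k) = log_sum_exp(buf.data(), K) + E(off + i, k);
      }
    for (int k = 0; k < K; ++k) beta(L - 1, k) = 0.0;
    for (int i = L - 2; i >= 0; --i)
      for (int k = 0; k < K; ++k) {
        for (int j = 0; j < K; ++j)
          buf[j] = Tw(k, j) + E(off + i + 1, j) + beta(i + 1, j);
        beta(i, k) = log_sum_exp(buf.data(), K);
      }
    for (int k = 0; k < K; ++k) buf[k] = alpha(L - 1, k);
    const double lz = log_sum_exp(buf.data(), K);
    logZ[s] = lz;
    for (int i = 0; i < L; ++i)
      for (int k = 0; k < K; ++k)
        marg(off + i, k) = std::exp(alpha(i, k) + beta(i, k) - lz);
    for (int i = 0; i + 1 < L; ++i)
      for (int a = 0; a < K; ++a)
        for (int b = 0; b < K; ++b)
          trans_exp(a, b) += std::exp(alpha(i, a) + Tw(a, b) +
                                      E(off + i + 1, b) + beta(i + 1, b) - lz);
    off += L;
  }
  return List::create(_["marginals"] = marg, _["logZ"] = logZ,
                      _["trans_exp"] = trans_exp);
}

// Backward-recursion partition function, used to cross-check the
// forward pass (both must give the same log Z).
// [[Rcpp::export]]
NumericVector crf_logz_backward(NumericMatrix E, NumericMatrix Tw, IntegerVector lens) {
  const int K = E.ncol();
  const int nseq = lens.size();
  NumericVector logZ(nseq);
  std::vector<double> buf(K);
  int off = 0;
  for (int s = 0; s < nseq; ++s) {
    const int L = lens[s];
    NumericMatrix beta(L, K);
    for (int k = 0; k < K; ++k) beta(L - 1, k) = 0.0;
    for (int i = L - 2; i >= 0; --i)
      for (int k = 0; k < K; ++k) {
        for (int j = 0; j < K; ++j)
          buf[j] = Tw(k, j) + E(off + i + 1, j) + beta(i + 1, j);
        beta(i, k) = log_sum_exp(buf.data(), K);
      }
    for (int k = 0; k < K; ++k) buf[k] = E(off, k) + beta(0, k);
    logZ[s] = log_sum_exp(buf.data(), K);
    off += L;
  }
  return logZ;
}

// Max-product decoding; ties are broken toward the lower state index.
// [[Rcpp::export]]
IntegerVector crf_viterbi(NumericMatrix E, NumericMatrix Tw, IntegerVector lens) {
  const int K = E.ncol();
  const int nseq = lens.size();
  IntegerVector path(E.nrow());
  int off = 0;
  for (int s = 0; s < nseq; ++s) {
    const int L = lens[s];
    NumericMatrix delta(L, K);
    IntegerMatrix back(L, K);
    for (int k = 0; k < K; ++k) delta(0, k) = E(off, k);
    for (int i = 1; i < L; ++i)
      for (int k = 0; k < K; ++k) {
        double best = delta(i - 1, 0) + Tw(0, k);
        int arg = 0;
        for (int j = 1; j < K; ++j) {
          const double v = delta(i - 1, j) + Tw(j, k);
          if (v > best) { best = v; arg = j; }
        }
        delta(i, k) = best + E(off + i, k);
        back(i, k) = arg;
      }
    int arg = 0;
    double best = delta(L - 1, 0);
    for (int k = 1; k < K; ++k)
      if (delta(L - 1, k) > best) { best = delta(L - 1, k); arg = k; }
    path[off + L - 1] = arg;
    for (int i = L - 1; i > 0; --i) {
      arg = back(i, arg);
      path[off + i - 1] = arg;
    }
    off += L;
  }
  return path;
}
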