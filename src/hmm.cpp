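#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Scaled forward-backward over a set of concatenated chains.
//
// x, n      per-SNP maternal / total read counts (concatenated chains)
// starts    0-based chain offsets, length n_chains + 1, last element = length(x)
// p         binomial success probabilities for states (S, M, P)
// trans     3x3 row-stochastic transition matrix, state order (S, M, P)
// init      initial state distribution
//
// Per-position scaling constants keep every quantity in linear space without
// underflow; the summed log scale factors give the exact log-likelihood.
// [[Rcpp::export]]
List fb_sufficient_stats(IntegerVector x, IntegerVector n, IntegerVector starts,
                         NumericVector p, NumericMatrix trans,
                         NumericVector init) {
  const int L = x.size();
  const int K = 3;
  const int nchain = starts.size() - 1;
  if (L == 0) stop("empty observation set");
  if (starts[0] != 0 || starts[nchain] != L)
    stop("chain offsets do not span the observations");

  NumericMatrix gamma(L, K);
  NumericMatrix xi(K, K);
  NumericVector chain_loglik(nchain);
  double loglik = 0.0;

  std::vector<double> emis(static_cast<size_t>(L) * K);
  for (int t = 0; t < L; ++t)
    for (int k = 0; k < K; ++k)
      emis[static_cast<size_t>(t) * K + k] = R::dbinom(x[t], n[t], p[k], 0);

  std::vector<double> alpha(static_cast<size_t>(L) * K);
  std::vector<double> beta(static_cast<size_t>(L) * K);
  std::vector<double> cvec(L);

  for (int c = 0; c < nchain; ++c) {
    const int s = starts[c], e = starts[c + 1];
    if (e <= s) stop("empty chain");
    double ll = 0.0, csum = 0.0;

    for (int k = 0; k < K; ++k) {
      alpha[static_cast<size_t>(s) * K + k] =
          init[k] * emis[static_cast<size_t>(s) * K + k];
      csum += alpha[static_cast<size_t>(s) * K + k];
    }
    if (!(csum > 0)) stop("zero forward probability: degenerate emission parameters");
    for (int k = 0; k < K; ++k) alpha[static_cast<size_t>(s) * K + k] /= csum;
    cvec[s] = csum;
    ll += std::log(csum);

    for (int t = s + 1; t < e; ++t) {
      csum = 0.0;
      for (int k = 0; k < K; ++k) {
        double a = 0.0;
        for (int j = 0; j < K; ++j)
          a += alpha[static_cast<size_t>(t - 1) * K + j] * trans(j, k);
        a *= emis[static_cast<size_t>(t) * K + k];
        alpha[static_cast<size_t>(t) * K + k] = a;
        csum += a;
      }
      if (!(csum > 0)) stop("zero forward probability: degenerate emission parameters");
      for (int k = 0; k < K; ++k) alpha[static_cast<size_t>(t) * K + k] /= csum;
      cvec[t] = csum;
      ll += std::log(csum);
    }

    for (int k = 0; k < K; ++k) beta[static_cast<size_t>(e - 1) * K + k] = 1.0;
    for (int t = e - 2; t >= s; --t) {
      for (int j = 0; j < K; ++j) {
        double b = 0.0;
        for (int k = 0; k < K; ++k)
          b += trans(j, k) * emis[static_cast<size_t>(t + 1) * K + k] *
               beta[static_cast<size_t>(t + 1) * K + k];
        beta[static_cast<size_t>(t) * K + j] = b / cvec[t + 1];
      }
    }

    for (int t = s; t < e; ++t)
      for (int k = 0; k < K; ++k)
        gamma(t, k) = alpha[static_cast<size_t>(t) * K + k] *
                      beta[static_cast<size_t>(t) * K + k];

    for (int t = s; t + 1 < e; ++t)
      for (int j = 0; j < K; ++j)
        for (int k = 0; k < K; ++k)
          xi(j, k) += alpha[static_cast<size_t>(t) * K + j] * trans(j, k) *
                      emis[static_cast<size_t>(t + 1) * K + k] *
                      beta[static_cast<size_t>(t + 1) * K + k] / cvec[t + 1];

    chain_loglik[c] = ll;
    loglik += ll;
  }

  return List::create(_["gamma"] = gamma, _["xi"] = xi,
                      _["loglik"] = loglik,
                      _["chain_loglik"] = chain_loglik);
}

// Log-space Viterbi decoding over concatenated chains; returns 0-based state
// indices in order (S, M, P). Exact ties keep the lowest state index, so the
// preference order is S > M > P.
// [[Rcpp::export]]
IntegerVector viterbi_cpp(IntegerVector x, IntegerVector n, IntegerVector starts,
                          NumericVector p, NumericMatrix trans,
                          NumericVector init) {
  const int L = x.size();
  const int K = 3;
  const int nchain = starts.size() - 1;
  if (L == 0) stop("empty observation set");

  IntegerVector path(L);
  std::vector<double> lemis(static_cast<size_t>(L) * K);
  for (int t = 0; t < L; ++t)
    for (int k = 0; k < K; ++k)
      lemis[static_cast<size_t>(t) * K + k] = R::dbinom(x[t], n[t], p[k], 1);

  double ltrans[3][3], linit[3];
  for (int j = 0; j < K; ++j) {
    linit[j] = std::log(init[j]);
    for (int k = 0; k < K; ++k) ltrans[j][k] = std::log(trans(j, k));
  }

  std::vector<double> delta(static_cast<size_t>(L) * K);
  std::vector<int> psi(static_cast<size_t>(L) * K);

  for (int c = 0; c < nchain; ++c) {
    const int s = starts[c], e = starts[c + 1];
    for (int k = 0; k < K; ++k)
      delta[static_cast<size_t>(s) * K + k] =
          linit[k] + lemis[static_cast<size_t>(s) * K + k];
    for (int t = s + 1; t < e; ++t) {
      for (int k = 0; k < K; ++k) {
        double best = -std::numeric_limits<double>::infinity();
        int arg = 0;
        for (int j = 0; j < K; ++j) {
          const double v = delta[static_cast<size_t>(t - 1) * K + j] + ltrans[j][k];
          if (v > best) { best = v; arg = j; }
        }
        delta[static_cast<size_t>(t) * K + k] =
            best + lemis[static_cast<size_t>(t) * K + k];
        psi[static_cast<size_t>(t) * K + k] = arg;
      }
    }
    double best = -std::numeric_limits<double>::infinity();
    int arg = 0;
    for (int k = 0; k < K; ++k) {
      const double v = delta[static_cast<size_t>(e - 1) * K + k];
      if (v > best) { best = v; arg = k; }
    }
    path[e - 1] = arg;
    for (int t = e - 2; t >= s; --t)
      path[t] = psi[static_cast<size_t>(t + 1) * K + path[t + 1]];
  }
  return path;
}
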