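#include <Rcpp.h>
using namespace Rcpp;

// Supervised ancestry EM: for each individual i, maximise
//   sum_j g_ij log(p_ij) + (2 - g_ij) log(1 - p_ij),  p_ij = sum_k q_ik f_jk
// over the simplex, with the standard multiplicative EM update.
// G: n x J integer dosages (NA = missing); F: J x K clamped parental
// frequencies. Each row iterates until its log-likelihood gain drops
// below tol or max_iter is reached.
// [[Rcpp::export(name = ".em_ancestry")]]
List em_ancestry(IntegerMatrix G, NumericMatrix F, double tol, int max_iter,
                 bool trace) {
  const int n = G.nrow(), J = G.ncol(), K = F.ncol();
  NumericMatrix Q(n, K);
  NumericVector loglik(n);
  IntegerVector iters(n);
  List traces(trace ? n : 0);
  std::vector<double> q(K), qn(K);
  // contiguous row-major copy of F for cache-friendly inner loops
  std::vector<double> f(static_cast<size_t>(J) * K);
  for (int j = 0; j < J; ++j)
    for (int k = 0; k < K; ++k) f[static_cast<size_t>(j) * K + k] = F(j, k);
  std::vector<int> gi(J);

  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < J; ++j) gi[j] = G(i, j);
    for (int k = 0; k < K; ++k) q[k] = 1.0 / K;
    double ll_old = R_NegInf, ll = 0.0;
    int it = 0;
    std::vector<double> hist;
    for (it = 0; it < max_iter; ++it) {
      // E step quantities and log-likelihood at current q
      ll = 0.0;
      std::fill(qn.begin(), qn.end(), 0.0);
      for (int j = 0; j < J; ++j) {
        const int g = gi[j];
        if (g == NA_INTEGER) continue;
        const double* fj = &f[static_cast<size_t>(j) * K];
        double pj = 0.0;
        for (int k = 0; k < K; ++k) pj += q[k] * fj[k];
        ll += g * std::log(pj) + (2 - g) * std::log1p(-pj);
        const double w1 = g / pj, w0 = (2 - g) / (1.0 - pj);
        for (int k = 0; k < K; ++k) {
          qn[k] += q[k] * (w1 * fj[k] + w0 * (1.0 - fj[k]));
        }
      }
      if (trace) hist.push_back(ll);
      if (ll - ll_old < tol && it > 0) break;
      ll_old = ll;
      double tot = 0.0;
      for (int k = 0; k < K; ++k) tot += qn[k];
      for (int k = 0; k < K; ++k) q[k] = qn[k] / tot;
    }
    for (int k = 0; k < K; ++k) Q(i, k) = q[k];
    loglik[i] = ll;
    iters[i] = it;
    if (trace) traces[i] = wrap(hist);
  }
  return List::create(_["Q"] = Q, _["loglik"] = loglik, _["iters"] = iters,
                      _["trace"] = traces);
}
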