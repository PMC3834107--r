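// Fast evaluation of the profile (maximized) log-likelihood of a causal
// ordering from per-gene sufficient statistics. This is the inner loop of
// the Metropolis-Hastings sampler: for gene j at position t of the
// ordering, regress on the t-1 preceding genes using the crossproduct
// matrix C[,,j] of the samples where j is not clamped, centered within
// those samples, and accumulate the Gaussian profile term.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
double profile_loglik_cpp(const arma::cube& C, const arma::vec& Nj,
                          const arma::ivec& ord, double sigma_floor) {
  const int p = ord.n_elem;
  const double l2pi = std::log(2.0 * M_PI);
  double ll = 0.0;
  for (int t = 0; t < p; ++t) {
    const int j = ord[t] - 1;
    const double nj = Nj[j];
    if (nj <= 0.0) continue;
    const arma::mat& Cj = C.slice(j);
    double rss;
    if (t == 0) {
      rss = Cj(j, j);
    } else {
      arma::uvec P(t);
      for (int s = 0; s < t; ++s) P[s] = ord[s] - 1;
      arma::mat A = Cj.submat(P, P);
      arma::uvec jj(1);
      jj[0] = j;
      arma::vec b = Cj.submat(P, jj);
      arma::vec w;
      bool ok = arma::solve(w, A, b,
                            arma::solve_opts::likely_sympd +
                            arma::solve_opts::no_approx);
      if (!ok) {
        // rank-deficient normal equations: any least-squares solution
        // gives the same residual sum of squares; use the min-norm one.
        arma::mat Ainv = arma::pinv(A, 1e-10 * arma::norm(A, 2));
        w = Ainv * b;
      }
      rss = Cj(j, j) - arma::dot(b, w);
      if (rss < 0.0) rss = 0.0;
    }
    double s = std::sqrt(rss / nj);
    if (s < sigma_floor) s = sigma_floor;
    ll += -0.5 * l2pi * nj - nj * std::log(s) - 0.5 * rss / (s * s);
  }
  return ll;
}
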