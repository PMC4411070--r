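// Hot path of the collapsed sampler: the marginal Gaussian log-likelihood
// of the log pond counts given the hyperparameters, with every Gaussian
// layer (global means, intercept field, coefficient field) integrated out.
// One dense Cholesky of the n x n marginal covariance per call.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// r: centered observations (log ponds minus log-area offset), length n
// si0: zero-based stratum index per observation
// Xn: n x P non-intercept design, FFt: n x n fixed-effect cross-product
// D2: S x S squared distance matrix
// [[Rcpp::export(name = ".marginalLoglikCpp")]]
double marginalLoglikCpp(const arma::vec& r, const arma::uvec& si0,
                         const arma::mat& Xn, const arma::mat& FFt,
                         const arma::mat& Dsq, double sigma0,
                         const arma::vec& sigb, const arma::vec& tau,
                         const arma::mat& rho, double phi0, double phiB,
                         double mu_sd2) {
  const uword n = r.n_elem;
  mat C = mu_sd2 * FFt;
  if (sigma0 > 0.0) {
    mat K0 = exp(-phi0 * phi0 * Dsq);
    C += (sigma0 * sigma0) * K0.submat(si0, si0);
  }
  if (any(sigb > 0.0)) {
    mat T = (sigb * sigb.t()) % rho;
    mat KB = exp(-phiB * phiB * Dsq);
    C += KB.submat(si0, si0) % (Xn * T * Xn.t());
  }
  vec d = tau.elem(si0);
  C.diag() += d % d;
  mat L;
  if (!chol(L, C, "lower")) return -datum::inf;
  vec z = solve(trimatl(L), r);
  return -0.5 * (n * std::log(2.0 * M_PI) + 2.0 * accu(log(L.diag())) +
                 dot(z, z));
}
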