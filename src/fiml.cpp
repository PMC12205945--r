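// FIML multivariate-normal -2 log-likelihood kernel.
// Families are grouped by (zygosity, missingness pattern) in R; each group
// shares one marginal covariance while the mean matrix stays free per row.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// Gradient companion: returns the -2lnL gradient with respect to the two
// 4x4 covariance matrices and the mean matrix. dL/dSigma (marginal) is
// n S^-1 - S^-1 W S^-1 with W the residual scatter; dL/dM rows are
// -2 (y - M) S^-1.
// [[Rcpp::export]]
Rcpp::List fiml_grad_kernel(const arma::mat& y, const arma::mat& M,
                            const arma::mat& sigma_mz,
                            const arma::mat& sigma_dz,
                            const Rcpp::List& rows0, const Rcpp::List& slots0,
                            const arma::ivec& zyg_mz) {
  arma::mat Gmz(4, 4, arma::fill::zeros), Gdz(4, 4, arma::fill::zeros);
  arma::mat dM(y.n_rows, 4, arma::fill::zeros);
  for (int g = 0; g < rows0.size(); ++g) {
    arma::uvec r = Rcpp::as<arma::uvec>(rows0[g]);
    arma::uvec s = Rcpp::as<arma::uvec>(slots0[g]);
    const arma::mat& sig = zyg_mz[g] == 1 ? sigma_mz : sigma_dz;
    arma::mat S = sig.submat(s, s);
    if (!S.is_finite())
      return Rcpp::List::create(Rcpp::Named("ok") = false);
    S = 0.5 * (S + S.t());
    arma::mat Sinv;
    bool ok = false;
    try { ok = arma::inv_sympd(Sinv, S); } catch (...) { ok = false; }
    if (!ok) return Rcpp::List::create(Rcpp::Named("ok") = false);
    arma::mat R = y.submat(r, s) - M.submat(r, s);
    arma::mat U = R * Sinv;
    arma::mat Gm = r.n_elem * Sinv - U.t() * U;
    if (zyg_mz[g] == 1) Gmz.submat(s, s) += Gm; else Gdz.submat(s, s) += Gm;
    dM.submat(r, s) = -2.0 * U;
  }
  return Rcpp::List::create(Rcpp::Named("ok") = true,
                            Rcpp::Named("Gmz") = Gmz,
                            Rcpp::Named("Gdz") = Gdz,
                            Rcpp::Named("dM") = dM);
}

// [[Rcpp::export]]
double fiml_neg2ll_kernel(const arma::mat& y, const arma::mat& M,
                          const arma::mat& sigma_mz,
                          const arma::mat& sigma_dz,
                          const Rcpp::List& rows0, const Rcpp::List& slots0,
                          const arma::ivec& zyg_mz, double penalty) {
  const double log2pi = std::log(2.0 * M_PI);
  double total = 0.0;
  for (int g = 0; g < rows0.size(); ++g) {
    arma::uvec r = Rcpp::as<arma::uvec>(rows0[g]);
    arma::uvec s = Rcpp::as<arma::uvec>(slots0[g]);
    const arma::mat& sig = zyg_mz[g] == 1 ? sigma_mz : sigma_dz;
    arma::mat S = sig.submat(s, s);
    if (!S.is_finite()) return 10.0 * penalty;
    S = 0.5 * (S + S.t());  // guard against last-ulp asymmetry
    arma::mat ch;
    bool ok = false;
    try { ok = arma::chol(ch, S); } catch (...) { ok = false; }
    if (!ok || ch.diag().min() < 1e-10)
      return penalty + arma::accu(arma::abs(S));
    double logdet = 2.0 * arma::accu(arma::log(ch.diag()));
    arma::mat R = y.submat(r, s) - M.submat(r, s);
    // quadratic form via triangular solve: Z = L^{-1} R', sum Z^2
    arma::mat Z;
    bool solved = false;
    try {
      solved = arma::solve(Z, arma::trimatl(ch.t()), R.t(),
                           arma::solve_opts::no_approx);
    } catch (...) {
      solved = false;
    }
    if (!solved)
      return penalty + arma::accu(arma::abs(S));
    total += r.n_elem * (s.n_elem * log2pi + logdet) +
      arma::accu(arma::square(Z));
  }
  return total;
}
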