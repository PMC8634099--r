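// Maximum-likelihood fit of a Gaussian precision matrix with a fixed
// off-diagonal zero pattern, by cyclic regression updates of the implied
// covariance (the classical iterative algorithm for covariance selection).
// At convergence the implied covariance W matches S exactly on the diagonal
// and on every allowed edge, and the precision is zero elsewhere.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// [[Rcpp::export(name = ".ips_fit_cpp")]]
Rcpp::List ips_fit_cpp(const arma::mat& S, const arma::imat& mask,
                       double tol, int max_iter) {
  const uword p = S.n_rows;
  mat W = S;

  // neighbor index lists, in the (p-1)-dimensional "others" coordinates
  std::vector<uvec> nb_others(p), others_all(p);
  for (uword j = 0; j < p; ++j) {
    uvec oth(p - 1);
    uword c = 0;
    for (uword i = 0; i < p; ++i) if (i != j) oth(c++) = i;
    others_all[j] = oth;
    std::vector<uword> nb;
    for (uword k = 0; k < p - 1; ++k)
      if (mask(oth(k), j) != 0) nb.push_back(k);
    nb_others[j] = uvec(nb);
  }

  bool converged = false;
  int iter = 0;
  for (iter = 0; iter < max_iter && !converged; ++iter) {
    double maxchg = 0.0;
    for (uword j = 0; j < p; ++j) {
      const uvec& oth = others_all[j];
      const uvec& nb = nb_others[j];
      vec w12_new(p - 1, fill::zeros);
      if (nb.n_elem > 0) {
        mat W11 = W.submat(oth, oth);
        vec s12 = S.col(j);
        vec s12nb(nb.n_elem);
        for (uword k = 0; k < nb.n_elem; ++k) s12nb(k) = s12(oth(nb(k)));
        vec beta_nb = solve(W11.submat(nb, nb), s12nb, solve_opts::likely_sympd);
        w12_new = W11.cols(nb) * beta_nb;
      }
      for (uword k = 0; k < p - 1; ++k) {
        double chg = std::abs(W(oth(k), j) - w12_new(k));
        if (chg > maxchg) maxchg = chg;
        W(oth(k), j) = w12_new(k);
        W(j, oth(k)) = w12_new(k);
      }
    }
    if (maxchg < tol) converged = true;
  }

  // recover the precision matrix from the final regression coefficients
  mat K(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    const uvec& oth = others_all[j];
    const uvec& nb = nb_others[j];
    vec beta(p - 1, fill::zeros);
    if (nb.n_elem > 0) {
      mat W11 = W.submat(oth, oth);
      vec s12 = S.col(j);
      vec s12nb(nb.n_elem);
      for (uword k = 0; k < nb.n_elem; ++k) s12nb(k) = s12(oth(nb(k)));
      vec beta_nb = solve(W11.submat(nb, nb), s12nb, solve_opts::likely_sympd);
      for (uword k = 0; k < nb.n_elem; ++k) beta(nb(k)) = beta_nb(k);
    }
    vec w12 = W.col(j);
    double quad = 0.0;
    for (uword k = 0; k < p - 1; ++k) quad += w12(oth(k)) * beta(k);
    double kjj = 1.0 / (S(j, j) - quad);
    K(j, j) = kjj;
    for (uword k = 0; k < p - 1; ++k)
      if (beta(k) != 0.0) K(oth(k), j) = -beta(k) * kjj;
  }
  K = 0.5 * (K + K.t());
  // enforce exact zeros off the mask (symmetrization noise)
  for (uword j = 0; j < p; ++j)
    for (uword i = 0; i < p; ++i)
      if (i != j && mask(i, j) == 0) K(i, j) = 0.0;

  return Rcpp::List::create(
    Rcpp::Named("precision") = K,
    Rcpp::Named("implied_cov") = W,
    Rcpp::Named("iterations") = iter,
    Rcpp::Named("converged") = converged);
}
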