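#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Coordinate descent for the lasso problem
//   min_alpha 0.5 * ||x - D alpha||_2^2 + lambda * ||alpha||_1
// solved simultaneously for every column of X. Inputs are the Gram matrix
// G = D'D (m x m) and the correlation matrix C = D'X (m x n). Atoms with
// G(i,i) ~ 0 (zero atoms) get coefficient 0. Convergence is declared when
// the largest coefficient change in a full sweep falls below tol.
// [[Rcpp::export]]
arma::mat cd_lasso(const arma::mat& G, const arma::mat& C, double lambda,
                   arma::mat alpha, int max_sweeps, double tol) {
  const arma::uword m = G.n_rows;
  const arma::uword n = C.n_cols;
  if (alpha.n_rows != m || alpha.n_cols != n)
    Rcpp::stop("alpha has inconsistent dimensions");
  arma::mat GA = G * alpha;  // running G %*% alpha, updated rank-1
  arma::rowvec delta(n);
  for (int s = 0; s < max_sweeps; ++s) {
    double maxdel = 0.0;
    for (arma::uword i = 0; i < m; ++i) {
      const double gii = G(i, i);
      if (gii <= 1e-12) {
        // degenerate atom: force its coefficients to zero
        bool any_nz = false;
        for (arma::uword j = 0; j < n; ++j) {
          delta(j) = -alpha(i, j);
          if (delta(j) != 0.0) any_nz = true;
          alpha(i, j) = 0.0;
        }
        if (any_nz) GA += G.col(i) * delta;
        continue;
      }
      bool changed = false;
      for (arma::uword j = 0; j < n; ++j) {
        const double z = alpha(i, j) * gii + C(i, j) - GA(i, j);
        double a_new = 0.0;
        if (z > lambda)       a_new = (z - lambda) / gii;
        else if (z < -lambda) a_new = (z + lambda) / gii;
        const double d = a_new - alpha(i, j);
        delta(j) = d;
        if (d != 0.0) {
          changed = true;
          alpha(i, j) = a_new;
          const double ad = std::abs(d);
          if (ad > maxdel) maxdel = ad;
        }
      }
      if (changed) GA += G.col(i) * delta;
    }
    if (maxdel < tol) break;
  }
  return alpha;
}
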