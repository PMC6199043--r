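// Graphical lasso by block coordinate descent (Friedman et al. style):
// W = S + rho*I; cycle over columns, solving each column's lasso
// subproblem by coordinate descent, then recover the precision matrix
// from the stored regression coefficients.
//
// The lasso subproblem for column j works with full-length p-vectors in
// which coordinate j is pinned to zero, so every inner product is a
// contiguous axpy on columns of W (no index gathers). Wb tracks W*beta
// incrementally.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List glasso_cd(const arma::mat& S, double rho, int max_iter,
                     double tol, int inner_max_iter = 50,
                     double inner_tol = 1e-5) {
  const uword p = S.n_rows;
  mat W = S;
  W.diag() += rho;
  mat Beta(p, p, fill::zeros);  // Beta(., j): coefficients for column j
  double off_mean = 0.0;
  {
    mat A = abs(S);
    A.diag().zeros();
    off_mean = accu(A) / std::max(1.0, double(p * (p - 1)));
  }
  const double thresh = tol * std::max(off_mean, 1e-12);
  bool converged = false;
  int iters = 0;

  for (int it = 0; it < max_iter; ++it) {
    double max_delta = 0.0;
    for (uword j = 0; j < p; ++j) {
      vec beta = Beta.col(j);
      beta(j) = 0.0;
      vec Wb(p, fill::zeros);  // W * beta (warm start)
      for (uword m = 0; m < p; ++m)
        if (beta(m) != 0.0) Wb += beta(m) * W.col(m);
      for (int in_it = 0; in_it < inner_max_iter; ++in_it) {
        double in_delta = 0.0;
        for (uword l = 0; l < p; ++l) {
          if (l == j) continue;
          const double wll = W(l, l);
          if (wll <= 0.0) continue;
          const double r = S(l, j) - Wb(l) + wll * beta(l);
          double bnew = 0.0;
          if (r > rho) bnew = (r - rho) / wll;
          else if (r < -rho) bnew = (r + rho) / wll;
          const double d = bnew - beta(l);
          if (d != 0.0) {
            Wb += d * W.col(l);
            beta(l) = bnew;
            const double ad = std::fabs(d);
            if (ad > in_delta) in_delta = ad;
          }
        }
        if (in_delta < inner_tol) break;
      }
      Beta.col(j) = beta;
      // w12 = W11 * beta, i.e. Wb restricted off the j-th coordinate
      for (uword l = 0; l < p; ++l) {
        if (l == j) continue;
        const double d = std::fabs(W(l, j) - Wb(l));
        if (d > max_delta) max_delta = d;
        W(l, j) = Wb(l);
        W(j, l) = Wb(l);
      }
    }
    iters = it + 1;
    if (max_delta < thresh) { converged = true; break; }
  }

  // recover Theta from the final W and regression coefficients
  mat Theta(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    const vec beta = Beta.col(j);
    double denom = W(j, j) - dot(W.col(j), beta) + W(j, j) * beta(j);
    if (denom <= 1e-12) denom = 1e-12;
    const double t22 = 1.0 / denom;
    Theta(j, j) = t22;
    for (uword l = 0; l < p; ++l)
      if (l != j) Theta(l, j) = -beta(l) * t22;
  }
  Theta = 0.5 * (Theta + Theta.t());

  return Rcpp::List::create(Rcpp::Named("theta") = Theta,
                            Rcpp::Named("w") = W,
                            Rcpp::Named("iterations") = iters,
                            Rcpp::Named("converged") = converged);
}
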