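#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// L2-penalized logistic regression along a decreasing lambda path.
// Objective: (1/n) * negloglik + lambda/2 * ||beta_-0||^2 (intercept
// unpenalized), matching the usual penalized-GLM scaling. Newton/IRLS with
// warm starts along the path; steps are damped to length <= 10 per
// coordinate, which is enough to make plain Newton globally convergent on
// this strictly convex objective.
// x: n x p standardized feature matrix (no intercept column); y: 0/1.
// Returns (p+1) x L coefficients, intercept first.
// [[Rcpp::export(name = ".ridge_logistic_path_cpp")]]
arma::mat ridge_logistic_path_cpp(const arma::mat& x,
                                  const arma::vec& y,
                                  const arma::vec& lambdas,
                                  const double tol = 1e-8,
                                  const int max_iter = 50) {
  const uword n = x.n_rows, p = x.n_cols, L = lambdas.n_elem;
  mat X(n, p + 1, fill::ones);
  X.cols(1, p) = x;
  vec pen(p + 1, fill::ones);
  pen(0) = 0.0;
  vec beta(p + 1, fill::zeros);
  mat out(p + 1, L, fill::zeros);
  for (uword l = 0; l < L; ++l) {
    const double lam = lambdas(l);
    for (int it = 0; it < max_iter; ++it) {
      vec eta = X * beta;
      vec mu = 1.0 / (1.0 + exp(-eta));
      vec w = mu % (1.0 - mu);
      w.transform([](double v) { return v < 1e-10 ? 1e-10 : v; });
      vec g = X.t() * (y - mu) / double(n) - lam * (pen % beta);
      mat H = X.t() * (X.each_col() % w) / double(n);
      H.diag() += lam * pen;
      vec delta = solve(H, g, solve_opts::likely_sympd);
      double sz = max(abs(delta));
      if (!std::isfinite(sz)) Rcpp::stop("Ridge logistic fit diverged.");
      if (sz > 10.0) delta *= 10.0 / sz;
      beta += delta;
      if (sz < tol) break;
    }
    out.col(l) = beta;
  }
  return out;
}
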