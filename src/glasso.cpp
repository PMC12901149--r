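#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Blockwise coordinate-descent graphical lasso (Friedman, Hastie &
// Tibshirani 2008). Estimates a penalized precision matrix from an
// empirical covariance S with L1 penalty rho on off-diagonal entries.
// Returns the covariance estimate W and precision estimate Theta.
// [[Rcpp::export(name = ".glasso_fit")]]
Rcpp::List glasso_fit(const arma::mat& S, double rho,
                      int maxit = 100, double tol = 1e-5,
                      int inner_maxit = 1000, double inner_tol = 1e-7) {
  const uword p = S.n_rows;
  if (S.n_cols != p) Rcpp::stop("S must be square");
  mat W = S;
  W.diag() += rho;
  mat B(p - 1, p, fill::zeros);  // lasso coefficients per column

  // average absolute off-diagonal of S for the convergence scale
  double soff = (accu(abs(S)) - accu(abs(S.diag()))) /
                std::max(1.0, double(p * (p - 1)));
  double thr = tol * std::max(soff, 1e-12);

  uvec all = regspace<uvec>(0, p - 1);
  bool converged = (p == 1);
  for (int it = 0; it < maxit && !converged; ++it) {
    double max_change = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec rest = find(all != j);
      mat W11 = W(rest, rest);
      vec s12 = S.col(j);
      s12 = s12(rest);
      vec beta = B.col(j);
      // coordinate descent for 0.5 b'W11 b - b's12 + rho|b|_1
      for (int ii = 0; ii < inner_maxit; ++ii) {
        double delta = 0.0;
        for (uword k = 0; k < p - 1; ++k) {
          double old = beta(k);
          double num = s12(k) - dot(W11.col(k), beta) + W11(k, k) * old;
          double val = soft(num, rho) / W11(k, k);
          beta(k) = val;
          delta = std::max(delta, std::fabs(val - old));
        }
        if (delta < inner_tol) break;
      }
      B.col(j) = beta;
      vec w12 = W11 * beta;
      for (uword k = 0; k < p - 1; ++k) {
        double old = W(rest(k), j);
        W(rest(k), j) = w12(k);
        W(j, rest(k)) = w12(k);
        max_change = std::max(max_change, std::fabs(w12(k) - old));
      }
    }
    if (max_change < thr) converged = true;
  }

  // back out the precision matrix from the final W and B
  mat Theta(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    uvec rest = find(all != j);
    vec beta = B.col(j);
    vec w12(p - 1);
    for (uword k = 0; k < p - 1; ++k) w12(k) = W(rest(k), j);
    double t22 = 1.0 / (W(j, j) - dot(w12, beta));
    Theta(j, j) = t22;
    for (uword k = 0; k < p - 1; ++k) Theta(rest(k), j) = -beta(k) * t22;
  }
  Theta = 0.5 * (Theta + Theta.t());

  return Rcpp::List::create(Rcpp::Named("w") = W,
                            Rcpp::Named("theta") = Theta,
                            Rcpp::Named("converged") = converged);
}
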