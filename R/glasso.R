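#' Graphical lasso on an empirical covariance
#'
#' L1-penalised maximum-likelihood estimation of a sparse precision matrix
#' by blockwise coordinate descent. Exact zeros in the off-diagonal of the
#' returned precision matrix define the conditional-independence structure.
#'
#' @param S Empirical covariance matrix (p x p, symmetric).
#' @param rho Non-negative L1 penalty on off-diagonal precision entries.
#' @param maxit,tol Outer-loop iteration cap and convergence tolerance
#'   (relative to the mean absolute off-diagonal covariance).
#' @return List with `w` (covariance estimate), `theta` (precision
#'   estimate) and `converged`.
#' @export
glasso_fit <- function(S, rho, maxit = 100, tol = 1e-5) {
  S <- as.matrix(S)
  if (!isSymmetric(S, tol = 1e-8)) stop("S must be symmetric")
  if (rho < 0) stop("rho must be non-negative")
  out <- .glasso_fit(S, rho, maxit = maxit, tol = tol)
  if (!out$converged) {
    stop(sprintf("graphical lasso did not converge at rho = %.4g", rho))
  }
  dimnames(out$w) <- dimnames(out$theta) <- dimnames(S)
  out
}

#' Cross-validated penalty selection for the graphical lasso
#'
#' Fits a logarithmic penalty grid, scores each penalty by the average
#' held-out Gaussian log-likelihood over k folds, and refits on the full
#' covariance at the selected penalty. The default selection rule is the
#' one-standard-error rule (the sparsest penalty whose CV score is within
#' one standard error of the optimum): maximising the CV likelihood alone
#' is known to over-select edges, so the 1-SE rule is the appropriate
#' choice when the estimand is the dependence structure rather than the
#' covariance itself. `rule = "max"` gives the plain CV optimum.
#'
#' @param X Data matrix, samples in rows, variables in columns.
#' @param n_alphas Number of grid points (log-spaced from the smallest
#'   penalty that empties the graph down to 1% of it).
#' @param n_folds Number of CV folds.
#' @param seed Integer seed for fold assignment.
#' @param rule Penalty selection rule: `"1se"` (default) or `"max"`.
#' @return List with `theta`, `w`, `rho` (selected penalty), `rhos` (the
#'   grid), `cv_loglik` and `cv_se` (mean and standard error of the
#'   held-out log-likelihood per grid point).
#' @export
glasso_cv <- function(X, n_alphas = 20, n_folds = 5, seed = 1,
                      rule = c("1se", "max")) {
  rule <- match.arg(rule)
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= 3) stop("need more than 3 samples")
  cov_ml <- function(Y) {
    Yc <- sweep(Y, 2L, colMeans(Y))
    crossprod(Yc) / nrow(Y)
  }
  S <- cov_ml(X)
  rho_max <- max(abs(S - diag(diag(S), p)))
  if (rho_max <= 0) rho_max <- 1e-3
  rhos <- exp(seq(log(rho_max), log(rho_max * 0.01), length.out = n_alphas))
  set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), n))
  ll <- matrix(NA_real_, n_folds, n_alphas)
  for (f in seq_len(n_folds)) {
    S_tr <- cov_ml(X[fold != f, , drop = FALSE])
    S_te <- cov_ml(X[fold == f, , drop = FALSE])
    for (a in seq_len(n_alphas)) {
      fit <- .glasso_fit(S_tr, rhos[a])
      if (!fit$converged) next
      ld <- determinant(fit$theta, logarithm = TRUE)
      if (ld$sign <= 0) next
      ll[f, a] <- as.numeric(ld$modulus) - sum(S_te * fit$theta)
    }
  }
  cv <- colMeans(ll)
  if (all(is.na(cv))) stop("graphical lasso CV failed along the whole penalty path")
  cv_se <- apply(ll, 2L, stats::sd) / sqrt(n_folds)
  best <- which.max(cv)
  pick <- if (rule == "1se") {
    # grid descends in rho, so the smallest index within 1 SE is sparsest
    min(which(cv >= cv[best] - cv_se[best]))
  } else best
  fit <- glasso_fit(S, rhos[pick])
  list(theta = fit$theta, w = fit$w, rho = rhos[pick], rhos = rhos,
       cv_loglik = cv, cv_se = cv_se)
}

#' Partial correlations from a precision matrix
#'
#' @param theta Precision matrix.
#' @return Matrix of partial correlations `-theta_uv / sqrt(theta_uu *
#'   theta_vv)` with unit diagonal.
#' @export
partial_correlations <- function(theta) {
  d <- sqrt(diag(theta))
  pc <- -theta / tcrossprod(d)
  diag(pc) <- 1
  pc
}
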