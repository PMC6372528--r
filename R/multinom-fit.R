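#' Weighted multinomial-logistic regression with a pinned reference class
#'
#' Maximizes the expected multinomial log-likelihood
#' `sum_n sum_m W[n, m] * log softmax(X B)[n, m]` over the coefficient
#' matrix `B` (one column per class, the reference column fixed at zero),
#' as needed by the EM maximization step where `W` holds fractional
#' posterior weights rather than one-hot responses. A tiny ridge penalty on
#' the slope (non-intercept) coefficients keeps the fit finite under
#' quasi-separation, e.g. when a covariate quadrant carries almost no
#' posterior mass.
#'
#' Optimization is quasi-Newton (BFGS) on the free columns with the
#' analytic gradient `X' (rowSums(W) * P - W)`.
#'
#' @param X n x p design matrix (first column the intercept)
#' @param W n x M nonnegative weight matrix
#' @param ref reference class whose column of `B` is fixed at zero
#' @param ridge L2 penalty on slope coefficients (intercepts unpenalized)
#' @param start optional p x M starting coefficient matrix
#' @param maxit maximum BFGS iterations
#' @return list with `coef` (p x M, reference column zero), `deviance`
#'   (`-2 *` weighted log-likelihood, unpenalized), `converged`,
#'   `evaluations`
#' @export
fit_multinom_weighted <- function(X, W, ref = 1L, ridge = 1e-6,
                                  start = NULL, maxit = 200L) {
  X <- as.matrix(X); W <- as.matrix(W)
  n <- nrow(X); p <- ncol(X); M <- ncol(W)
  stopifnot(nrow(W) == n, ref >= 1L, ref <= M, all(W >= 0))
  free <- setdiff(seq_len(M), ref)
  wrow <- rowSums(W)
  slope_mask <- matrix(rep(c(0, rep(1, p - 1L)), length(free)), p, length(free))

  unpack <- function(theta) {
    B <- matrix(0, p, M)
    B[, free] <- theta
    B
  }
  nll <- function(theta) {
    B <- unpack(theta)
    eta <- X %*% B
    eta <- eta - apply(eta, 1L, max)
    logZ <- log(rowSums(exp(eta)))
    -sum(W * (eta - logZ)) + 0.5 * ridge * sum((matrix(theta, p) * slope_mask)^2)
  }
  grad <- function(theta) {
    B <- unpack(theta)
    eta <- X %*% B
    eta <- eta - apply(eta, 1L, max)
    P <- exp(eta) / rowSums(exp(eta))
    G <- crossprod(X, wrow * P - W)            # p x M
    as.vector(G[, free]) + ridge * as.vector(matrix(theta, p) * slope_mask)
  }

  theta0 <- if (is.null(start)) rep(0, p * length(free)) else {
    start <- as.matrix(start)
    stopifnot(nrow(start) == p, ncol(start) == M)
    as.vector(start[, free] - start[, ref])
  }
  opt <- stats::optim(theta0, nll, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  B <- unpack(opt$par)
  eta <- X %*% B
  eta <- eta - apply(eta, 1L, max)
  ll <- sum(W * (eta - log(rowSums(exp(eta)))))
  list(coef = B, deviance = -2 * ll, converged = opt$convergence == 0L,
       evaluations = unname(opt$counts[1L]))
}
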