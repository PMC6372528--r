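#' Numerically stable softmax
#'
#' Normalized exponential with max-subtraction, so adding a constant to all
#' logits leaves the result unchanged and no intermediate overflows.
#'
#' @param logits numeric vector, or matrix (applied row-wise)
#' @return probability vector/matrix with rows summing to 1
#' @export
softmax <- function(logits) {
  if (is.matrix(logits)) {
    z <- logits - apply(logits, 1L, max)
    e <- exp(z)
    return(e / rowSums(e))
  }
  z <- logits - max(logits)
  e <- exp(z)
  e / sum(e)
}

.SIGMA_FLOOR <- 1e-3

#' Parameters of a covariate-dependent Gaussian HMM
#'
#' The model has `M` latent states with Gaussian emissions on the scaled
#' difficulty axis (`mu`, `sigma`), a multinomial-logistic initial-state
#' model with design `[1, init_covariates]`, and per-origin-state
#' multinomial-logistic transition models with design
#' `[1, trans_covariates]`. One destination class per regression is the
#' reference whose coefficient column is pinned to zero; probabilities are
#' invariant to this choice.
#'
#' @param mu,sigma emission means and standard deviations (length `M`;
#'   `sigma` is floored at 1e-3)
#' @param init_coef `(1+q_I) x M` coefficient matrix for the initial-state
#'   logits (`NULL` for all-zero, i.e. uniform)
#' @param trans_coef `(1+q_h) x M x M` array, `[predictor, destination,
#'   origin]` (`NULL` for all-zero, i.e. uniform rows)
#' @param init_covariates,trans_covariates covariate names (without
#'   intercept) in the canonical order used by [build_designs()]
#' @param ref reference (zero-column) class index, default 1
#' @return an object of class `hmm_params`
#' @export
hmm_params <- function(mu, sigma, init_coef = NULL, trans_coef = NULL,
                       init_covariates = character(), trans_covariates = character(),
                       ref = 1L) {
  M <- length(mu)
  stopifnot(M >= 1L, length(sigma) == M, ref >= 1L, ref <= M)
  sigma <- pmax(sigma, .SIGMA_FLOOR)
  qI <- length(init_covariates)
  qh <- length(trans_covariates)
  if (is.null(init_coef)) init_coef <- matrix(0, 1L + qI, M)
  if (is.null(trans_coef)) trans_coef <- array(0, c(1L + qh, M, M))
  init_coef <- as.matrix(init_coef)
  stopifnot(nrow(init_coef) == 1L + qI, ncol(init_coef) == M)
  stopifnot(length(dim(trans_coef)) == 3L,
            all(dim(trans_coef) == c(1L + qh, M, M)))
  if (max(abs(init_coef[, ref])) > 1e-8 || max(abs(trans_coef[, ref, ])) > 1e-8) {
    stop("reference-class column of the coefficient blocks must be zero")
  }
  rownames(init_coef) <- c("(Intercept)", init_covariates)
  dimnames(trans_coef) <- list(c("(Intercept)", trans_covariates), NULL, NULL)
  structure(list(M = M, mu = mu, sigma = sigma,
                 init_coef = init_coef, trans_coef = trans_coef,
                 init_covariates = init_covariates,
                 trans_covariates = trans_covariates,
                 ref = as.integer(ref)),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat(sprintf("hmm_params: %d states, ref class %d\n", x$M, x$ref))
  cat("  mu:   ", paste(sprintf("%.3f", x$mu), collapse = " "), "\n")
  cat("  sigma:", paste(sprintf("%.3f", x$sigma), collapse = " "), "\n")
  cat("  initial covariates: ",
      if (length(x$init_covariates)) paste(x$init_covariates, collapse = ", ") else "(intercept only)", "\n")
  cat("  transition covariates: ",
      if (length(x$trans_covariates)) paste(x$trans_covariates, collapse = ", ") else "(intercept only)", "\n")
  invisible(x)
}

# Shift every logit column so that column `ref` is zero; probabilities are
# unchanged (softmax shift invariance).
.pin_reference <- function(params, ref = 1L) {
  params$init_coef <- params$init_coef - params$init_coef[, ref]
  for (l in seq_len(params$M)) {
    params$trans_coef[, , l] <- params$trans_coef[, , l] - params$trans_coef[, ref, l]
  }
  params$ref <- as.integer(ref)
  params
}

#' Initial-state probabilities
#'
#' Evaluates the multinomial-logistic initial-state model at covariate
#' row(s) `I` (intercept included).
#'
#' @param params an [hmm_params()]
#' @param I design vector of length `1+q_I`, or an `n x (1+q_I)` matrix
#' @return probability vector over states, or an `n x M` matrix
#' @export
initial_probs <- function(params, I = NULL) {
  if (is.null(I)) I <- rep(1, 1L)
  if (!is.matrix(I)) {
    if (length(I) != nrow(params$init_coef)) stop("initial design length mismatch")
    return(softmax(drop(I %*% params$init_coef)))
  }
  if (ncol(I) != nrow(params$init_coef)) stop("initial design dimension mismatch")
  softmax(I %*% params$init_coef)
}

#' Transition probability matrix at one covariate setting
#'
#' Evaluates the per-origin-state multinomial-logistic transition models at
#' the covariate row `h` (intercept included), returning the full
#' row-stochastic M x M matrix.
#'
#' @param params an [hmm_params()]
#' @param h design vector of length `1+q_h`
#' @return M x M matrix, rows = origin state, each summing to 1
#' @export
transition_matrix <- function(params, h = NULL) {
  if (is.null(h)) h <- rep(1, 1L)
  if (length(h) != dim(params$trans_coef)[1L]) stop("transition design length mismatch")
  M <- params$M
  P <- matrix(NA_real_, M, M)
  for (l in seq_len(M)) {
    P[l, ] <- softmax(drop(h %*% params$trans_coef[, , l]))
  }
  P
}

# Row-wise transition probabilities out of origin l for a design matrix H
# (n x (1+q_h)): returns n x M.
.trans_probs_origin <- function(params, H, l) {
  softmax(H %*% params$trans_coef[, , l])
}

# ---------------------------------------------------------------------------
# Stacked representation: all participants share T, so the forward-backward
# recursions run vectorized over participants.

.prepare_stack <- function(dataset, params_or_spec, mode = "inclusive") {
  spec <- list(init_covariates = params_or_spec$init_covariates,
               trans_covariates = params_or_spec$trans_covariates)
  designs <- build_designs(dataset, spec, mode = mode)
  list(Y = scale_levels(dataset$level), I = designs$I, H = designs$H,
       n = dataset$n, T = dataset$T)
}

# Emission densities scaled by the per-observation maximum so the forward
# pass cannot underflow: Bs[[j]] is n x M with max 1 per row, k[, j] holds
# the subtracted log maxima.
.scaled_emissions <- function(params, Y) {
  n <- nrow(Y); T_len <- ncol(Y); M <- params$M
  Bs <- vector("list", T_len)
  k <- matrix(NA_real_, n, T_len)
  for (j in seq_len(T_len)) {
    logb <- vapply(seq_len(M), function(m) {
      stats::dnorm(Y[, j], params$mu[m], params$sigma[m], log = TRUE)
    }, numeric(n))
    logb <- matrix(logb, nrow = n)
    mx <- apply(logb, 1L, max)
    Bs[[j]] <- exp(logb - mx)
    k[, j] <- mx
  }
  list(Bs = Bs, k = k)
}

# Full scaled forward-backward pass over the stacked dataset.
# Returns gamma [n,M,T], xi [n,M,M,T-1], per-sequence and total loglik.
.forward_backward <- function(params, stack) {
  n <- stack$n; T_len <- stack$T; M <- params$M
  em <- .scaled_emissions(params, stack$Y)
  pi1 <- initial_probs(params, stack$I)
  if (!is.matrix(pi1)) pi1 <- matrix(pi1, n, M, byrow = TRUE)

  alpha <- array(NA_real_, c(n, M, T_len))
  cs <- matrix(NA_real_, n, T_len)
  a <- pi1 * em$Bs[[1L]]
  cs[, 1L] <- rowSums(a)
  alpha[, , 1L] <- a / cs[, 1L]

  trans <- vector("list", T_len)  # trans[[j]][[l]]: n x M, P(l -> .) into item j
  if (T_len >= 2L) {
    for (j in 2:T_len) {
      Pl <- lapply(seq_len(M), function(l) .trans_probs_origin(params, stack$H[[j]], l))
      trans[[j]] <- Pl
      apred <- matrix(0, n, M)
      for (l in seq_len(M)) apred <- apred + alpha[, l, j - 1L] * Pl[[l]]
      a <- apred * em$Bs[[j]]
      cs[, j] <- rowSums(a)
      alpha[, , j] <- a / cs[, j]
    }
  }
  loglik_i <- rowSums(log(cs)) + rowSums(em$k)

  gamma <- array(NA_real_, c(n, M, T_len))
  xi <- if (T_len >= 2L) array(NA_real_, c(n, M, M, T_len - 1L)) else NULL
  beta <- matrix(1, n, M)
  gamma[, , T_len] <- alpha[, , T_len] * beta
  if (T_len >= 2L) {
    for (j in T_len:2L) {
      tmp <- em$Bs[[j]] * beta / cs[, j]          # n x M
      beta_new <- matrix(NA_real_, n, M)
      for (l in seq_len(M)) {
        Plm <- trans[[j]][[l]] * tmp              # n x M
        xi[, l, , j - 1L] <- alpha[, l, j - 1L] * Plm
        beta_new[, l] <- rowSums(Plm)
      }
      beta <- beta_new
      gamma[, , j - 1L] <- alpha[, , j - 1L] * beta
    }
  }
  list(gamma = gamma, xi = xi, loglik_i = loglik_i, loglik = sum(loglik_i))
}

#' Expectation step: posterior state and transition probabilities
#'
#' Runs the scaled forward-backward recursion with per-item transition
#' matrices and returns the posterior state memberships `gamma`
#' (participants x states x items), joint transition posteriors `xi`
#' (participants x origin x destination x items-1, where slab `j` covers
#' the transition from item `j` to `j+1`), and the exact marginal
#' log-likelihood.
#'
#' @param params an [hmm_params()]
#' @param dataset a [process_dataset()]
#' @param mode accumulation mode for the transition covariates
#' @return list with `gamma`, `xi`, `loglik_i` (per participant), `loglik`
#' @export
e_step <- function(params, dataset, mode = c("inclusive", "lagged")) {
  mode <- match.arg(mode)
  stack <- .prepare_stack(dataset, params, mode = mode)
  .forward_backward(params, stack)
}

#' Log-likelihood of a single observation sequence
#'
#' Marginal log density of one scaled choice sequence under the model,
#' computed by the protected forward pass. Designs default to
#' intercept-only; supply `I` (length `1+q_I`) and `H` (`T x (1+q_h)`,
#' rows 2..T used) for covariate models.
#'
#' @param params an [hmm_params()]
#' @param y scaled observations (values in (0,1\], e.g. level/7), length T
#' @param I initial-state design vector (defaults to intercept only)
#' @param H transition design matrix (defaults to intercept only)
#' @return log-likelihood (scalar)
#' @export
sequence_loglik <- function(params, y, I = NULL, H = NULL) {
  T_len <- length(y)
  if (T_len == 0L) stop("empty sequence")
  qI <- length(params$init_covariates)
  qh <- length(params$trans_covariates)
  if (is.null(I)) {
    if (qI > 0L) stop("model has initial covariates; supply I")
    I <- rep(1, 1L)
  }
  if (is.null(H)) {
    if (qh > 0L) stop("model has transition covariates; supply H")
    H <- matrix(1, T_len, 1L)
  }
  Hl <- vector("list", T_len)
  if (T_len >= 2L) for (j in 2:T_len) Hl[[j]] <- matrix(H[j, ], 1L)
  stack <- list(Y = matrix(y, 1L), I = matrix(I, 1L), H = Hl, n = 1L, T = T_len)
  .forward_backward(params, stack)$loglik
}

#' Maximization step
#'
#' Updates the parameters from the posteriors of [e_step()]: emission means
#' and SDs are gamma-weighted moments pooled over participants and items;
#' the initial-state block is a weighted multinomial-logistic fit of the
#' item-1 memberships on `I`; each origin state's transition block is a
#' weighted multinomial-logistic fit of the `xi` slabs on `h`. With no
#' covariates the logistic fits reduce to the closed-form normalized
#' expected counts. Reference-class columns stay pinned to zero.
#'
#' @param posterior output of [e_step()]
#' @param dataset a [process_dataset()]
#' @param spec a [model_def()]
#' @param mode accumulation mode for the transition covariates
#' @param start optional [hmm_params()] used to warm-start the inner
#'   logistic fits
#' @param ridge tiny L2 penalty on slope (non-intercept) coefficients of
#'   the inner fits, guarding against quasi-separation
#' @return updated [hmm_params()]
#' @export
m_step <- function(posterior, dataset, spec, mode = c("inclusive", "lagged"),
                   start = NULL, ridge = 1e-6) {
  mode <- match.arg(mode)
  M <- dim(posterior$gamma)[2L]
  designs <- build_designs(dataset, spec, mode = mode)
  Y <- scale_levels(dataset$level)
  n <- dataset$n; T_len <- dataset$T

  # Emissions: pooled gamma-weighted moments.
  gflat <- matrix(aperm(posterior$gamma, c(1L, 3L, 2L)), n * T_len, M)  # (i,j) x m
  yflat <- as.vector(Y)
  wsum <- colSums(gflat)
  mu <- colSums(gflat * yflat) / wsum
  sigma <- sqrt(colSums(gflat * (outer(yflat, mu, "-"))^2) / wsum)
  sigma <- pmax(sigma, .SIGMA_FLOOR)

  ref <- if (is.null(start)) 1L else start$ref
  init_cov <- colnames(designs$I)[-1L]
  trans_cov <- if (T_len >= 2L) colnames(designs$H[[2L]])[-1L] else character()

  # Initial-state block.
  g1 <- posterior$gamma[, , 1L, drop = FALSE][, , 1L]
  if (!is.matrix(g1)) g1 <- matrix(g1, n, M)
  if (length(init_cov) == 0L) {
    p1 <- pmax(colMeans(g1), 1e-12)
    init_coef <- matrix(log(p1) - log(p1[ref]), 1L, M)
  } else {
    fit <- fit_multinom_weighted(designs$I, g1, ref = ref, ridge = ridge,
                                 start = if (!is.null(start)) start$init_coef else NULL)
    if (!fit$converged) {
      warning(sprintf("initial-state logistic fit did not converge (%d evaluations)",
                      fit$evaluations))
    }
    init_coef <- fit$coef
  }

  # Transition blocks, one weighted multinomial regression per origin state.
  trans_coef <- array(0, c(1L + length(trans_cov), M, M))
  if (T_len >= 2L) {
    if (length(trans_cov) == 0L) {
      counts <- apply(posterior$xi, c(2L, 3L), sum)      # origin x dest
      for (l in seq_len(M)) {
        pl <- pmax(counts[l, ] / sum(counts[l, ]), 1e-12)
        trans_coef[, , l] <- log(pl) - log(pl[ref])
      }
    } else {
      Hall <- do.call(rbind, designs$H[2:T_len])          # (n*(T-1)) x (1+q_h)
      for (l in seq_len(M)) {
        Wl <- matrix(aperm(posterior$xi[, l, , , drop = FALSE], c(1L, 4L, 3L, 2L)),
                     n * (T_len - 1L), M)
        fit <- fit_multinom_weighted(Hall, Wl, ref = ref, ridge = ridge,
                                     start = if (!is.null(start)) start$trans_coef[, , l] else NULL)
        if (!fit$converged) {
          warning(sprintf("transition logistic fit for origin state %d did not converge (%d evaluations)",
                          l, fit$evaluations))
        }
        trans_coef[, , l] <- fit$coef
      }
    }
  }

  hmm_params(mu, sigma, init_coef, trans_coef,
             init_covariates = init_cov, trans_covariates = trans_cov, ref = ref)
}

#' EM control settings
#'
#' @param tol relative log-likelihood convergence tolerance
#'   (`|dLL| / (1 + |LL|) < tol` stops the outer loop)
#' @param max_iter maximum outer EM iterations
#' @param n_restarts number of EM runs; the first uses the deterministic
#'   quantile initialization, later ones jitter the starting means with
#'   seed-controlled Gaussian noise
#' @param seed integer seed driving the restart jitter (required when
#'   `n_restarts > 1`)
#' @param jitter_sd standard deviation of the restart mean jitter, on the
#'   scaled difficulty axis
#' @param ridge L2 penalty on inner-fit slopes, see [m_step()]
#' @param verbose print the outer-iteration log-likelihood trace
#' @return list of class `em_control`
#' @export
em_control <- function(tol = 1e-8, max_iter = 500L, n_restarts = 1L,
                       seed = NULL, jitter_sd = 0.08, ridge = 1e-6,
                       verbose = FALSE) {
  if (n_restarts > 1L && is.null(seed)) {
    stop("n_restarts > 1 requires a seed for the restart jitter")
  }
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 n_restarts = as.integer(n_restarts), seed = seed,
                 jitter_sd = jitter_sd, ridge = ridge, verbose = verbose),
            class = "em_control")
}

# Deterministic default start: emission means at the (m - 0.5)/M quantiles
# of pooled scaled y, SDs at the pooled SD, logit coefficients zero.
.init_params <- function(dataset, spec, mu_jitter = NULL) {
  y <- as.vector(scale_levels(dataset$level))
  M <- spec$M
  mu <- as.numeric(stats::quantile(y, probs = (seq_len(M) - 0.5) / M))
  if (!is.null(mu_jitter)) mu <- mu + mu_jitter
  sigma <- rep(max(stats::sd(y), .SIGMA_FLOOR), M)
  qI <- length(spec$init_covariates)
  qh <- length(spec$trans_covariates)
  hmm_params(mu, sigma,
             init_coef = matrix(0, 1L + qI, M),
             trans_coef = array(0, c(1L + qh, M, M)),
             init_covariates = spec$init_covariates,
             trans_covariates = spec$trans_covariates)
}

#' Fit a covariate-dependent Gaussian HMM by EM
#'
#' Alternates [e_step()] and [m_step()] until the relative log-likelihood
#' change falls below `control$tol` or `control$max_iter` is reached. With
#' `control$n_restarts > 1`, additional runs start from jittered emission
#' means and the highest-log-likelihood solution is returned. The outer
#' log-likelihood trace is monotone non-decreasing up to numerical
#' tolerance (EM ascent); states are returned in estimation order — use
#' [relabel_states()] for ascending-mean reporting order.
#'
#' @param dataset a [process_dataset()]
#' @param spec a [model_def()]
#' @param control an [em_control()]
#' @param mode accumulation mode for the transition covariates
#' @return object of class `hmm_fit`: `params`, `loglik`, `npar`, `aic`,
#'   `bic`, `posterior` (final [e_step()] output), `trace`, `converged`,
#'   `iterations`, `restarts` (per-restart summary), `spec`, `n_obs`, `mode`
#' @export
fit_em <- function(dataset, spec, control = em_control(),
                   mode = c("inclusive", "lagged")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "process_dataset"))
  if (!is.null(control$seed)) set.seed(control$seed)

  run_once <- function(mu_jitter) {
    params <- .init_params(dataset, spec, mu_jitter = mu_jitter)
    trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    post <- NULL
    for (it in seq_len(control$max_iter)) {
      post <- e_step(params, dataset, mode = mode)
      trace <- c(trace, post$loglik)
      if (control$verbose) {
        message(sprintf("  iter %3d  logLik %.6f", it, post$loglik))
      }
      if (is.finite(ll_old) &&
          abs(post$loglik - ll_old) / (1 + abs(post$loglik)) < control$tol) {
        converged <- TRUE
        break
      }
      ll_old <- post$loglik
      params <- m_step(post, dataset, spec, mode = mode, start = params,
                       ridge = control$ridge)
    }
    list(params = params, posterior = post, trace = trace,
         converged = converged, iterations = length(trace))
  }

  runs <- vector("list", control$n_restarts)
  for (k in seq_len(control$n_restarts)) {
    jit <- if (k == 1L) NULL else stats::rnorm(spec$M, 0, control$jitter_sd)
    runs[[k]] <- tryCatch(run_once(jit), error = function(e) e)
  }
  ok <- !vapply(runs, inherits, logical(1L), "error")
  if (!any(ok)) {
    stop("all EM restarts failed; first error: ",
         conditionMessage(runs[[1L]]))
  }
  lls <- vapply(runs[ok], function(r) r$posterior$loglik, numeric(1L))
  best <- runs[ok][[which.max(lls)]]

  npar <- count_params(spec)
  n_obs <- dataset$n * dataset$T
  structure(list(
    params = best$params,
    loglik = best$posterior$loglik,
    npar = npar,
    n_obs = n_obs,
    aic = aic(best$posterior$loglik, npar),
    bic = bic(best$posterior$loglik, npar, n_obs),
    posterior = best$posterior,
    trace = best$trace,
    converged = best$converged,
    iterations = best$iterations,
    restarts = data.frame(
      restart = which(ok),
      loglik = lls,
      converged = vapply(runs[ok], `[[`, logical(1L), "converged"),
      iterations = vapply(runs[ok], `[[`, integer(1L), "iterations")
    ),
    spec = spec,
    mode = mode,
    n = dataset$n,
    T = dataset$T
  ), class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("hmm_fit: model %s (%d states), %d participants x %d items\n",
              x$spec$name, x$spec$M, x$n, x$T))
  cat(sprintf("  logLik %.3f  (k = %d, AIC %.2f, BIC %.2f)\n",
              x$loglik, x$npar, x$aic, x$bic))
  cat(sprintf("  EM: %d iterations, %s, %d restart(s)\n", x$iterations,
              if (x$converged) "converged" else "NOT converged",
              nrow(x$restarts)))
  invisible(x)
}

#' @export
logLik.hmm_fit <- function(object, ...) {
  structure(object$loglik, df = object$npar, nobs = object$n_obs,
            class = "logLik")
}

#' Viterbi decoding of the most probable state paths
#'
#' Computes, per participant, the jointly most probable latent state
#' sequence under the time-varying transition model, with ties broken
#' toward the lowest state index.
#'
#' @param params an [hmm_params()]
#' @param dataset a [process_dataset()]
#' @param mode accumulation mode for the transition covariates
#' @return list with `states` (participants x items integer matrix of
#'   state indices in estimation order) and `logp` (per-participant log
#'   probability of the decoded path, including the emission terms)
#' @export
viterbi <- function(params, dataset, mode = c("inclusive", "lagged")) {
  mode <- match.arg(mode)
  stack <- .prepare_stack(dataset, params, mode = mode)
  n <- stack$n; T_len <- stack$T
  states <- matrix(NA_integer_, n, T_len,
                   dimnames = list(rownames(stack$Y), NULL))
  logp <- numeric(n)
  for (i in seq_len(n)) {
    H_i <- matrix(1, T_len, dim(params$trans_coef)[1L])
    if (T_len >= 2L) for (j in 2:T_len) H_i[j, ] <- stack$H[[j]][i, ]
    res <- .viterbi_one(params, stack$Y[i, ], I = stack$I[i, ], H = H_i)
    states[i, ] <- res$path
    logp[i] <- res$logp
  }
  list(states = states, logp = logp)
}

# Core single-sequence Viterbi; H rows 2..T are used (row 1 ignored).
.viterbi_one <- function(params, y, I, H) {
  T_len <- length(y); M <- params$M
  logB <- vapply(seq_len(M), function(m) {
    stats::dnorm(y, params$mu[m], params$sigma[m], log = TRUE)
  }, numeric(T_len))
  logB <- matrix(logB, nrow = T_len)
  delta <- log(initial_probs(params, I)) + logB[1L, ]
  psi <- matrix(NA_integer_, M, T_len)
  if (T_len >= 2L) {
    for (j in 2:T_len) {
      logP <- log(transition_matrix(params, H[j, ]))
      cand <- delta + logP                    # origin x dest
      psi[, j] <- apply(cand, 2L, which.max)  # first max = lowest state index
      delta <- cand[cbind(psi[, j], seq_len(M))] + logB[j, ]
    }
  }
  path <- integer(T_len)
  path[T_len] <- which.max(delta)
  if (T_len >= 2L) for (j in T_len:2L) path[j - 1L] <- psi[path[j], j]
  list(path = path, logp = delta[path[T_len]])
}

#' Viterbi decoding of a single sequence
#'
#' Single-sequence counterpart of [viterbi()] taking explicit design
#' inputs; defaults to intercept-only designs as in [sequence_loglik()].
#'
#' @inheritParams sequence_loglik
#' @return list with `path` (integer states) and `logp` (joint log
#'   probability of the decoded path and the observations)
#' @export
viterbi_sequence <- function(params, y, I = NULL, H = NULL) {
  T_len <- length(y)
  if (T_len == 0L) stop("empty sequence")
  qI <- length(params$init_covariates)
  qh <- length(params$trans_covariates)
  if (is.null(I)) {
    if (qI > 0L) stop("model has initial covariates; supply I")
    I <- rep(1, 1L)
  }
  if (is.null(H)) {
    if (qh > 0L) stop("model has transition covariates; supply H")
    H <- matrix(1, T_len, 1L)
  }
  .viterbi_one(params, y, I, H)
}
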