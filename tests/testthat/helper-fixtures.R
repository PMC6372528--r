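# Shared fixtures: small parameter sets, toy datasets, and brute-force
# oracles used to validate the forward and Viterbi recursions.

# A well-separated three-state intercept-only model (sticky chain).
toy_params_b <- function() {
  pi1 <- c(0.36, 0.45, 0.19)
  P <- rbind(c(0.93, 0.05, 0.02),
             c(0.04, 0.92, 0.04),
             c(0.04, 0.06, 0.90))
  trans <- array(0, c(1, 3, 3))
  for (l in 1:3) trans[1, , l] <- log(P[l, ]) - log(P[l, 1])
  hmm_params(mu = c(0.19, 0.51, 0.86), sigma = c(0.07, 0.12, 0.13),
             init_coef = matrix(log(pi1) - log(pi1[1]), 1),
             trans_coef = trans)
}

# A random full-covariate model (covariates as in the most general rung).
toy_params_cov <- function(seed = 1) {
  set.seed(seed)
  ic <- matrix(stats::rnorm(4 * 3, 0, 0.5), 4, 3); ic[, 1] <- 0
  tc <- array(stats::rnorm(8 * 9, 0, 0.4), c(8, 3, 3)); tc[, 1, ] <- 0
  hmm_params(mu = c(0.2, 0.5, 0.8), sigma = c(0.1, 0.12, 0.09), ic, tc,
             init_covariates = c("d", "p", "dp"),
             trans_covariates = c("d", "f", "r", "fr", "df", "dr", "dfr"))
}

# Exhaustive path-sum log-likelihood (oracle for the forward pass).
brute_loglik <- function(params, y, I = rep(1, 1), H = matrix(1, length(y), 1)) {
  T_len <- length(y)
  M <- params$M
  pi1 <- initial_probs(params, I)
  Ps <- if (T_len >= 2) lapply(2:T_len, function(j) transition_matrix(params, H[j, ]))
  paths <- as.matrix(expand.grid(rep(list(seq_len(M)), T_len)))
  lik <- 0
  for (k in seq_len(nrow(paths))) {
    s <- paths[k, ]
    p <- pi1[s[1]] * stats::dnorm(y[1], params$mu[s[1]], params$sigma[s[1]])
    if (T_len >= 2) for (j in 2:T_len) {
      p <- p * Ps[[j - 1]][s[j - 1], s[j]] *
        stats::dnorm(y[j], params$mu[s[j]], params$sigma[s[j]])
    }
    lik <- lik + p
  }
  log(lik)
}

# Exhaustive most-probable-path search (oracle for Viterbi).
brute_viterbi <- function(params, y, I = rep(1, 1), H = matrix(1, length(y), 1)) {
  T_len <- length(y)
  M <- params$M
  pi1 <- initial_probs(params, I)
  Ps <- if (T_len >= 2) lapply(2:T_len, function(j) transition_matrix(params, H[j, ]))
  paths <- as.matrix(expand.grid(rep(list(seq_len(M)), T_len)))
  lp <- vapply(seq_len(nrow(paths)), function(k) {
    s <- paths[k, ]
    p <- log(pi1[s[1]]) + stats::dnorm(y[1], params$mu[s[1]], params$sigma[s[1]], log = TRUE)
    if (T_len >= 2) for (j in 2:T_len) {
      p <- p + log(Ps[[j - 1]][s[j - 1], s[j]]) +
        stats::dnorm(y[j], params$mu[s[j]], params$sigma[s[j]], log = TRUE)
    }
    p
  }, numeric(1))
  list(path = as.integer(paths[which.max(lp), ]), logp = max(lp))
}

# Hand-built long-format frame for a tiny valid cohort.
tiny_long <- function(n = 2, T_len = 3) {
  data.frame(
    participant = rep(seq_len(n), each = T_len),
    item = rep(seq_len(T_len), n),
    level = rep_len(c(1L, 4L, 7L, 3L, 2L, 5L), n * T_len),
    correct = rep_len(c(1L, 0L, 1L), n * T_len),
    confidence = rep_len(c(0.8, 0.5, 0.3), n * T_len),
    condition = rep(rep_len(c(1L, 0L), n), each = T_len),
    pretest = rep(rep_len(c(0.8, 0.6), n), each = T_len)
  )
}
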