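# JSON layout for fitted models: M, mu, sigma, named coefficient blocks,
# reference class, and (for fits) fit metadata. Coefficient matrices are
# stored column-per-state so the round trip is exact.

.params_to_list <- function(params) {
  cols <- function(m) lapply(seq_len(ncol(m)), function(j) unname(m[, j]))
  M <- params$M
  list(
    M = M,
    mu = params$mu,
    sigma = params$sigma,
    ref = params$ref,
    init_covariates = as.list(params$init_covariates),
    trans_covariates = as.list(params$trans_covariates),
    init_coef = cols(params$init_coef),
    trans_coef = lapply(seq_len(M), function(l) {
      cols(matrix(params$trans_coef[, , l], ncol = M))
    })
  )
}

.params_from_list <- function(x) {
  M <- x$M
  init_cov <- unlist(x$init_covariates) %||% character()
  trans_cov <- unlist(x$trans_covariates) %||% character()
  init_coef <- do.call(cbind, lapply(x$init_coef, unlist))
  trans_coef <- array(0, c(1L + length(trans_cov), M, M))
  for (l in seq_len(M)) {
    trans_coef[, , l] <- do.call(cbind, lapply(x$trans_coef[[l]], unlist))
  }
  hmm_params(unlist(x$mu), unlist(x$sigma), init_coef, trans_coef,
             init_covariates = init_cov, trans_covariates = trans_cov,
             ref = x$ref)
}

#' Serialize a fitted model (or bare parameters) to JSON
#'
#' Writes a documented JSON layout: `M`, `mu`, `sigma`, coefficient blocks
#' with their covariate names, the reference class, and -- when given a
#' full [fit_em()] result -- fit metadata (model name, log-likelihood,
#' parameter count, AIC/BIC, iterations, convergence flag, accumulation
#' mode, data dimensions). [read_hmm_json()] restores an [hmm_params()]
#' bit-for-bit.
#'
#' @param x an [hmm_params()] or an `hmm_fit` from [fit_em()]
#' @param path output JSON path
#' @export
write_hmm_json <- function(x, path) {
  if (inherits(x, "hmm_fit")) {
    out <- list(
      params = .params_to_list(x$params),
      fit = list(model = x$spec$name, loglik = x$loglik, npar = x$npar,
                 n_obs = x$n_obs, aic = x$aic, bic = x$bic,
                 iterations = x$iterations, converged = x$converged,
                 mode = x$mode, n = x$n, T = x$T)
    )
  } else if (inherits(x, "hmm_params")) {
    out <- list(params = .params_to_list(x))
  } else {
    stop("x must be an hmm_params or hmm_fit object")
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_hmm_json
#' @return `read_hmm_json()`: list with `params` (an [hmm_params()]) and
#'   `fit` (metadata list, `NULL` for bare parameter files)
#' @export
read_hmm_json <- function(path) {
  x <- jsonlite::read_json(path)
  list(params = .params_from_list(x$params), fit = x$fit)
}
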