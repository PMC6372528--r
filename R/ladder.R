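#' Model definitions for the comparison ladder
#'
#' The six models compared in the analysis differ in the number of latent
#' states and in the covariate sets of the initial-state and transition
#' regressions:
#'
#' * `A`:   2 states, intercept-only everywhere
#' * `B`:   3 states, intercept-only everywhere
#' * `B1`:  3 states, initial-state covariates `d, p, dp`
#' * `B2a`: B1 + transition covariate `d`
#' * `B2b`: B1 + transition covariates `f, r, fr`
#' * `B3`:  B1 + transition covariates `d, f, r, fr, df, dr, dfr`
#'
#' where `d` is the goal condition (1 = performance), `p` the pre-test
#' proportion correct, and `f`/`r` the accumulated confidence/correctness
#' tracks.
#'
#' @param name one of `"A"`, `"B"`, `"B1"`, `"B2a"`, `"B2b"`, `"B3"`, or
#'   `"custom"` (then supply `M`, `init_covariates`, `trans_covariates`)
#' @param M number of latent states (custom models only)
#' @param init_covariates,trans_covariates covariate names (custom models
#'   only)
#' @return list of class `model_def` with `name`, `M`, `init_covariates`,
#'   `trans_covariates`
#' @export
model_def <- function(name = c("A", "B", "B1", "B2a", "B2b", "B3", "custom"),
                      M = NULL, init_covariates = NULL, trans_covariates = NULL) {
  name <- match.arg(name)
  defs <- list(
    A   = list(M = 2L, init = character(), trans = character()),
    B   = list(M = 3L, init = character(), trans = character()),
    B1  = list(M = 3L, init = c("d", "p", "dp"), trans = character()),
    B2a = list(M = 3L, init = c("d", "p", "dp"), trans = "d"),
    B2b = list(M = 3L, init = c("d", "p", "dp"), trans = c("f", "r", "fr")),
    B3  = list(M = 3L, init = c("d", "p", "dp"),
               trans = c("d", "f", "r", "fr", "df", "dr", "dfr"))
  )
  if (name == "custom") {
    stopifnot(!is.null(M))
    def <- list(M = as.integer(M),
                init = init_covariates %||% character(),
                trans = trans_covariates %||% character())
  } else {
    def <- defs[[name]]
  }
  structure(list(name = name, M = def$M,
                 init_covariates = def$init, trans_covariates = def$trans),
            class = "model_def")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of free parameters in a model
#'
#' `2M` emission parameters, `(1 + q_I)(M - 1)` initial-state logit
#' coefficients (one class is the zero reference), and
#' `(1 + q_h) M (M - 1)` transition logit coefficients (one regression per
#' origin state, each with a reference destination).
#'
#' @param def a [model_def()]
#' @return integer parameter count
#' @export
count_params <- function(def) {
  M <- def$M
  qI <- length(def$init_covariates)
  qh <- length(def$trans_covariates)
  as.integer(2L * M + (1L + qI) * (M - 1L) + (1L + qh) * M * (M - 1L))
}

#' Information criteria
#'
#' `aic = -2 logLik + 2k`; `bic = -2 logLik + k log(n_obs)` with `n_obs`
#' the total number of item observations (participants x items).
#'
#' @param loglik maximized log-likelihood
#' @param k number of free parameters
#' @param n_obs number of observations entering the BIC penalty
#' @return criterion value (lower is better)
#' @export
aic <- function(loglik, k) -2 * loglik + 2 * k

#' @rdname aic
#' @export
bic <- function(loglik, k, n_obs) -2 * loglik + k * log(n_obs)

#' Likelihood-ratio test for nested models
#'
#' `chi2 = 2 (logLik_general - logLik_restricted)` referred to a
#' chi-square distribution with `df = k_general - k_restricted`. The usual
#' regularity conditions are asserted, not proven, for HMM covariate
#' tests; the p-value is the conventional naive reference.
#'
#' @param loglik_restricted,loglik_general maximized log-likelihoods
#' @param k_restricted,k_general parameter counts (general must exceed
#'   restricted)
#' @return list with `chi2`, `df`, `p`
#' @export
lrt <- function(loglik_restricted, loglik_general, k_restricted, k_general) {
  if (k_general <= k_restricted) {
    stop("general model must have more parameters than the restricted model")
  }
  chi2 <- 2 * (loglik_general - loglik_restricted)
  df <- k_general - k_restricted
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

# Nesting relation by covariate-set inclusion (same or larger M).
.is_nested <- function(restricted, general) {
  restricted$M <= general$M &&
    all(restricted$init_covariates %in% general$init_covariates) &&
    all(restricted$trans_covariates %in% general$trans_covariates)
}

# The reported LRT chain: each entry restricted -> general.
.lrt_chain <- list(c("B", "B1"), c("B1", "B2a"), c("B1", "B2b"), c("B2b", "B3"))

#' Fit the six-model comparison ladder
#'
#' Fits models A through B3 with shared EM control settings and assembles
#' the comparison table: parameter count, log-likelihood, AIC, BIC (with
#' `n_obs` = participants x items), and the likelihood-ratio chain
#' B in B1, B1 in B2a, B1 in B2b, B2b in B3.
#'
#' @param dataset a [process_dataset()]
#' @param control an [em_control()] shared by all rungs
#' @param models character vector of rung names to fit (default all six)
#' @param mode accumulation mode for the transition covariates
#' @return object of class `ladder_fit`: list with `fits` (named list of
#'   [fit_em()] results) and `table` (the comparison data frame)
#' @export
fit_ladder <- function(dataset, control = em_control(),
                       models = c("A", "B", "B1", "B2a", "B2b", "B3"),
                       mode = c("inclusive", "lagged")) {
  mode <- match.arg(mode)
  fits <- list()
  for (nm in models) {
    fits[[nm]] <- tryCatch(
      fit_em(dataset, model_def(nm), control = control, mode = mode),
      error = function(e) e
    )
  }
  structure(list(fits = fits,
                 table = comparison_table(fits, n_obs = dataset$n * dataset$T)),
            class = "ladder_fit")
}

#' Assemble a model-comparison table
#'
#' Builds the comparison table from fitted rungs (or from externally
#' supplied `loglik`/`k` values via `ladder_table_from_loglik()`), adding
#' the likelihood-ratio chain for the standard nested pairs present.
#'
#' @param fits named list of [fit_em()] results (failed rungs may be error
#'   conditions; they are annotated and skipped)
#' @param n_obs observation count for the BIC penalty
#' @return data frame with one row per model: `model`, `M`, `k`, `logLik`,
#'   `AIC`, `BIC`, `lrt_vs`, `chi2`, `df_diff`, `p`, `error`
#' @export
comparison_table <- function(fits, n_obs) {
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    if (inherits(f, "error")) {
      return(data.frame(model = nm, M = NA_integer_, k = NA_integer_,
                        logLik = NA_real_, AIC = NA_real_, BIC = NA_real_,
                        error = conditionMessage(f)))
    }
    data.frame(model = nm, M = f$spec$M, k = f$npar, logLik = f$loglik,
               AIC = aic(f$loglik, f$npar), BIC = bic(f$loglik, f$npar, n_obs),
               error = NA_character_)
  })
  tab <- do.call(rbind, rows)
  tab$lrt_vs <- NA_character_
  tab$chi2 <- NA_real_
  tab$df_diff <- NA_integer_
  tab$p <- NA_real_
  for (pair in .lrt_chain) {
    r <- pair[1L]; g <- pair[2L]
    if (r %in% tab$model && g %in% tab$model &&
        !is.na(tab$logLik[tab$model == r]) && !is.na(tab$logLik[tab$model == g])) {
      if (!.is_nested(model_def(r), model_def(g))) next
      res <- lrt(tab$logLik[tab$model == r], tab$logLik[tab$model == g],
                 tab$k[tab$model == r], tab$k[tab$model == g])
      i <- which(tab$model == g)
      tab$lrt_vs[i] <- r
      tab$chi2[i] <- res$chi2
      tab$df_diff[i] <- res$df
      tab$p[i] <- res$p
    }
  }
  tab[c("model", "M", "k", "logLik", "AIC", "BIC",
        "lrt_vs", "chi2", "df_diff", "p", "error")]
}

#' @export
print.ladder_fit <- function(x, ...) {
  cat("Model comparison ladder\n")
  print(x$table, digits = 8, row.names = FALSE)
  invisible(x)
}

#' Write a comparison table to CSV and/or JSON
#'
#' @param table comparison data frame from [comparison_table()]
#' @param csv,json output paths (either may be `NULL`)
#' @export
write_comparison <- function(table, csv = NULL, json = NULL) {
  if (!is.null(csv)) utils::write.csv(table, csv, row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(table, json, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(table)
}
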