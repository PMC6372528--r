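#' Relabel states in ascending order of emission mean
#'
#' EM estimation fixes the reference class by index, so the state order of
#' a fitted model is arbitrary. For reporting, states are sorted by
#' ascending emission mean (the low/medium/high convention); all
#' coefficient blocks are permuted consistently and the reference class is
#' re-pinned to the new first state by shifting the logit columns, which
#' leaves every probability unchanged. Tied means keep their original
#' relative order.
#'
#' @param params an [hmm_params()]
#' @param ref reference class index to pin after relabeling
#' @return list with `params` (relabeled) and `perm` (integer vector:
#'   `perm[k]` is the original index of new state `k`)
#' @export
relabel_states <- function(params, ref = 1L) {
  perm <- order(params$mu)
  M <- params$M
  out <- params
  out$mu <- params$mu[perm]
  out$sigma <- params$sigma[perm]
  out$init_coef <- params$init_coef[, perm, drop = FALSE]
  tc <- params$trans_coef[, perm, perm, drop = FALSE]
  out$trans_coef <- tc
  out <- .pin_reference(out, ref = ref)
  rownames(out$init_coef) <- rownames(params$init_coef)
  dimnames(out$trans_coef)[[1L]] <- dimnames(params$trans_coef)[[1L]]
  list(params = out, perm = perm)
}

#' Covariate grid for effect evaluation
#'
#' Expands named covariate value sets into a grid of evaluation points
#' (one row per combination); interaction terms are derived automatically
#' when the design rows are built.
#'
#' @param ... named vectors of covariate values, e.g.
#'   `d = c(0, 1), p = c(0, 0.5, 1)`
#' @return data frame with one row per grid point
#' @export
covariate_grid <- function(...) {
  vals <- list(...)
  stopifnot(length(vals) > 0, !is.null(names(vals)), all(names(vals) != ""))
  expand.grid(vals, KEEP.OUT.ATTRS = FALSE)
}

# States must be in ascending-mean order for the L/M/H labels to apply.
.state_labels <- function(M) {
  if (M == 3L) c("L", "M", "H") else paste0("S", seq_len(M))
}

.check_ascending <- function(params) {
  if (is.unsorted(params$mu)) {
    stop("states are not in ascending-mean order; apply relabel_states() first")
  }
}

#' Expected initial-state probabilities over a covariate grid
#'
#' Evaluates the initial-state multinomial-logit model at each grid point
#' (the numeric analogue of the stacked-bar effect displays). The model's
#' base covariates must all be present in the grid.
#'
#' @param params an [hmm_params()] in ascending-mean order (see
#'   [relabel_states()])
#' @param grid data frame from [covariate_grid()] with the model's base
#'   covariates (e.g. `d` and `p`)
#' @return data frame: grid columns, `state` label, `prob`
#' @export
expected_initial <- function(params, grid) {
  .check_ascending(params)
  base <- unique(unlist(strsplit(params$init_covariates, "")))
  missing <- setdiff(base, names(grid))
  if (length(missing)) {
    stop("grid lacks covariate(s): ", paste(missing, collapse = ", "))
  }
  labels <- .state_labels(params$M)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    I <- design_row(grid[g, , drop = FALSE], params$init_covariates)
    probs <- initial_probs(params, I)
    cbind(grid[rep(g, params$M), , drop = FALSE],
          data.frame(state = labels, prob = as.numeric(probs)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Expected transition probabilities over a covariate grid
#'
#' Evaluates the full transition matrix at each grid point and aggregates
#' each origin row into stay, upward, and downward mass (destinations
#' above/below the origin in the ascending-mean order).
#'
#' @param params an [hmm_params()] in ascending-mean order
#' @param grid data frame with the model's base transition covariates
#'   (e.g. `f` and `r`, plus `d` for condition-dependent models)
#' @return data frame: grid columns, `from`, `to`, `prob`, and the
#'   per-origin aggregates `stay`, `up`, `down` (repeated across the
#'   destinations of the row)
#' @export
expected_transitions <- function(params, grid) {
  .check_ascending(params)
  base <- unique(unlist(strsplit(params$trans_covariates, "")))
  missing <- setdiff(base, names(grid))
  if (length(missing)) {
    stop("grid lacks covariate(s): ", paste(missing, collapse = ", "))
  }
  labels <- .state_labels(params$M)
  M <- params$M
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    h <- design_row(grid[g, , drop = FALSE], params$trans_covariates)
    P <- transition_matrix(params, h)
    df <- data.frame(
      from = rep(labels, each = M),
      to = rep(labels, times = M),
      prob = as.numeric(t(P))
    )
    agg <- t(vapply(seq_len(M), function(l) {
      c(stay = P[l, l],
        up = if (l < M) sum(P[l, (l + 1L):M]) else 0,
        down = if (l > 1L) sum(P[l, seq_len(l - 1L)]) else 0)
    }, numeric(3L)))
    df$stay <- rep(agg[, "stay"], each = M)
    df$up <- rep(agg[, "up"], each = M)
    df$down <- rep(agg[, "down"], each = M)
    cbind(grid[rep(g, nrow(df)), , drop = FALSE], df)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an effect table as tidy CSV
#'
#' @param effects data frame from [expected_initial()] or
#'   [expected_transitions()]
#' @param path output CSV path
#' @export
write_effects <- function(effects, path) {
  utils::write.csv(effects, path, row.names = FALSE)
  invisible(path)
}
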