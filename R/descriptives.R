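#' Pooled distribution of difficulty choices
#'
#' Proportion of all participant-by-item choices at each of the seven
#' difficulty levels.
#'
#' @param dataset a [process_dataset()]
#' @return named numeric vector of length 7 summing to 1
#' @export
choice_distribution <- function(dataset) {
  stopifnot(inherits(dataset, "process_dataset"))
  tab <- tabulate(dataset$level, nbins = 7L)
  stats::setNames(tab / sum(tab), as.character(1:7))
}

#' Manifest up/down transition counts
#'
#' Counts strict increases (upward) and strict decreases (downward) in
#' each participant's level sequence; equal adjacent levels count as
#' neither.
#'
#' @param levels integer vector of one participant's levels, or a
#'   participants x items matrix
#' @return for a vector, `c(up = , down = )`; for a matrix, a data frame
#'   with one row per participant
#' @export
transition_counts <- function(levels) {
  if (is.matrix(levels)) {
    out <- t(apply(levels, 1L, transition_counts))
    return(data.frame(participant = rownames(levels),
                      up = out[, "up"], down = out[, "down"],
                      row.names = NULL))
  }
  d <- diff(levels)
  c(up = sum(d > 0), down = sum(d < 0))
}

#' Most frequent complete choice sequences
#'
#' Groups participants by their exact full level sequence and reports the
#' top `k` sequences by count, overall and split by goal condition. Ties
#' are broken by first occurrence.
#'
#' @param dataset a [process_dataset()]
#' @param k number of sequences to report per group
#' @return data frame with `group` (`"all"`, `"performance"`,
#'   `"learning"`), `rank`, `sequence` (dash-separated levels), `count`,
#'   `proportion` (of the group)
#' @export
frequent_sequences <- function(dataset, k = 10L) {
  stopifnot(inherits(dataset, "process_dataset"), k >= 1L)
  seq_str <- apply(dataset$level, 1L, paste, collapse = "-")
  top_k <- function(strs, group) {
    if (length(strs) == 0L) return(NULL)
    counts <- table(factor(strs, levels = unique(strs)))  # unique() = first occurrence
    ord <- order(-as.integer(counts))
    kk <- min(k, length(counts))
    data.frame(group = group, rank = seq_len(kk),
               sequence = names(counts)[ord][seq_len(kk)],
               count = as.integer(counts[ord][seq_len(kk)]),
               proportion = as.numeric(counts[ord][seq_len(kk)]) / length(strs))
  }
  out <- rbind(
    top_k(seq_str, "all"),
    top_k(seq_str[dataset$condition == 1], "performance"),
    top_k(seq_str[dataset$condition == 0], "learning")
  )
  rownames(out) <- NULL
  out
}

#' Pooled correlations among level, correctness, and confidence
#'
#' Point-biserial correlations of difficulty level and confidence with the
#' binary correctness indicator (computed as Pearson correlations with the
#' 0/1 coding, the standard equivalence), and the Pearson correlation of
#' level with confidence, over all participant-by-item observations.
#'
#' @param dataset a [process_dataset()]
#' @return named list: `level_correct` (r_pb), `confidence_correct`
#'   (r_pb), `level_confidence` (Pearson)
#' @export
association_stats <- function(dataset) {
  stopifnot(inherits(dataset, "process_dataset"))
  lev <- as.vector(dataset$level)
  cor_ <- as.vector(dataset$correct)
  conf <- as.vector(dataset$confidence)
  if (stats::sd(lev) == 0 || stats::sd(cor_) == 0 || stats::sd(conf) == 0) {
    stop("zero-variance input; correlations undefined")
  }
  list(level_correct = stats::cor(lev, cor_),
       confidence_correct = stats::cor(conf, cor_),
       level_confidence = stats::cor(lev, conf))
}

#' Average residual autocorrelation of difficulty choices
#'
#' Removes participant and item effects from the level sequences by
#' two-way fixed-effects demeaning (subtract the participant mean and the
#' item mean, add back the grand mean), computes each participant's
#' autocorrelation function of the residuals, and averages across
#' participants. Constant choosers (zero raw sequence variance) are
#' excluded with a warning: their demeaned residuals merely mirror the item
#' means and carry no within-person signal. Residual sequences that are
#' numerically degenerate are excluded on the same grounds.
#'
#' @param dataset a [process_dataset()]
#' @param max_lag largest lag to report (must be `< T`)
#' @return list with `acf` (named vector, lags `1..max_lag`),
#'   `n_used`, `n_excluded`
#' @export
residual_acf <- function(dataset, max_lag = 5L) {
  stopifnot(inherits(dataset, "process_dataset"), max_lag >= 1L,
            max_lag < dataset$T)
  lev <- dataset$level
  resid <- lev - rowMeans(lev) -
    matrix(colMeans(lev), dataset$n, dataset$T, byrow = TRUE) + mean(lev)
  v_raw <- apply(lev, 1L, stats::var)
  v_res <- apply(resid, 1L, stats::var)
  usable <- v_raw > 1e-12 & v_res > 1e-12
  if (any(!usable)) {
    warning(sprintf("%d constant or degenerate sequence(s) excluded from the ACF average",
                    sum(!usable)))
  }
  if (!any(usable)) stop("no participant with non-degenerate residuals")
  acfs <- t(apply(resid[usable, , drop = FALSE], 1L, function(x) {
    stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[-1L]
  }))
  acfs <- matrix(acfs, ncol = max_lag)
  list(acf = stats::setNames(colMeans(acfs), paste0("lag", seq_len(max_lag))),
       n_used = sum(usable), n_excluded = sum(!usable))
}

#' One-shot sequence summary
#'
#' Convenience wrapper bundling the descriptive analyses: choice
#' distribution, per-condition mean up/down transition counts, top-k
#' sequences, pooled correlations, and the average residual ACF.
#'
#' @param dataset a [process_dataset()]
#' @param k top-k for [frequent_sequences()]
#' @param max_lag for [residual_acf()]
#' @return list of class `sequence_summary`
#' @export
sequence_summary <- function(dataset, k = 10L, max_lag = 5L) {
  tc <- transition_counts(dataset$level)
  by_cond <- function(cond) {
    idx <- dataset$condition == cond
    c(up = mean(tc$up[idx]), down = mean(tc$down[idx]))
  }
  structure(list(
    n = dataset$n, T = dataset$T,
    choice_distribution = choice_distribution(dataset),
    transitions = list(performance = by_cond(1), learning = by_cond(0)),
    frequent_sequences = frequent_sequences(dataset, k = k),
    associations = association_stats(dataset),
    residual_acf = residual_acf(dataset, max_lag = max_lag)
  ), class = "sequence_summary")
}

#' @export
print.sequence_summary <- function(x, ...) {
  cat(sprintf("sequence_summary: %d participants x %d items\n", x$n, x$T))
  cat("  choice distribution (%):",
      paste(sprintf("%.1f", 100 * x$choice_distribution), collapse = " "), "\n")
  cat(sprintf("  mean transitions, performance: %.2f up / %.2f down; learning: %.2f up / %.2f down\n",
              x$transitions$performance["up"], x$transitions$performance["down"],
              x$transitions$learning["up"], x$transitions$learning["down"]))
  a <- x$associations
  cat(sprintf("  r(level,correct) = %.2f  r_pb(conf,correct) = %.2f  r(level,conf) = %.2f\n",
              a$level_correct, a$confidence_correct, a$level_confidence))
  cat(sprintf("  avg lag-1 residual ACF = %.2f (%d participants excluded)\n",
              x$residual_acf$acf["lag1"], x$residual_acf$n_excluded))
  invisible(x)
}

#' Export a sequence summary as JSON
#'
#' @param summary a [sequence_summary()]
#' @param path output JSON path
#' @export
write_summary <- function(summary, path) {
  out <- unclass(summary)
  out$frequent_sequences <- summary$frequent_sequences
  jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
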