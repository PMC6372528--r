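#' Assemble and validate a process dataset
#'
#' A process dataset holds one self-adapted test session per participant:
#' the sequence of chosen difficulty levels (integers 1--7), answer
#' correctness (0/1) and confidence ratings (unit scale), plus the
#' participant-level goal condition (1 = performance, 0 = learning) and
#' pre-test proportion correct. All participants must share the same number
#' of items; incomplete sequences are rejected rather than imputed.
#'
#' @param data long-format data frame with columns `participant`, `item`,
#'   `level`, `correct`, `confidence`, `condition`, `pretest`. Items must be
#'   contiguous `1..T` within each participant. `confidence` is expected on
#'   the unit scale here; [load_dataset()] rescales 0--100 input.
#' @param check_grid validate that confidence values sit on the 0.1 grid
#'   (ratings are collected in 10-point steps on a 0--100 scale). Set to
#'   `FALSE` for data whose confidence channel is continuous.
#' @return an object of class `process_dataset`: a list with the long
#'   `data`, the per-participant matrices `level`, `correct`, `confidence`
#'   (participants x items), vectors `condition` and `pretest`, participant
#'   ids, `n` and `T`.
#' @export
process_dataset <- function(data, check_grid = TRUE) {
  required <- c("participant", "item", "level", "correct", "confidence",
                "condition", "pretest")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  data <- as.data.frame(data)[required]

  bad_row <- function(cond, what) {
    idx <- which(cond)
    if (length(idx) > 0L) {
      stop(sprintf("%s (e.g. row %d: participant %s, item %s)",
                   what, idx[1L], data$participant[idx[1L]], data$item[idx[1L]]),
           call. = FALSE)
    }
  }
  bad_row(!(data$level %in% 1:7), "difficulty level outside 1..7")
  bad_row(!(data$correct %in% c(0, 1)), "correctness not in {0,1}")
  bad_row(!is.finite(data$confidence) | data$confidence < 0 | data$confidence > 1,
          "confidence outside [0,1] (expected unit scale)")
  if (check_grid) {
    off <- abs(data$confidence * 10 - round(data$confidence * 10)) > 1e-8
    bad_row(off, "confidence not on the 0.1 grid")
  }
  bad_row(!(data$condition %in% c(0, 1)), "condition not in {0,1}")
  bad_row(!is.finite(data$pretest) | data$pretest < 0 | data$pretest > 1,
          "pretest outside [0,1]")

  ids <- unique(data$participant)
  n <- length(ids)
  counts <- table(factor(data$participant, levels = ids))
  T_len <- as.integer(counts[[1L]])
  if (any(counts != T_len)) {
    bad <- names(counts)[counts != T_len][1L]
    stop(sprintf("inconsistent sequence length: participant %s has %d items, expected %d",
                 bad, counts[[bad]], T_len), call. = FALSE)
  }
  if (T_len < 1L) stop("each participant needs at least one item")

  ord <- order(match(data$participant, ids), data$item)
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL
  items_ok <- tapply(data$item, factor(data$participant, levels = ids),
                     function(x) identical(as.integer(x), seq_len(T_len)))
  if (!all(unlist(items_ok))) {
    bad <- ids[!unlist(items_ok)][1L]
    stop(sprintf("items not contiguous 1..%d for participant %s", T_len, bad),
         call. = FALSE)
  }

  to_mat <- function(col) {
    matrix(data[[col]], nrow = n, ncol = T_len, byrow = TRUE,
           dimnames = list(as.character(ids), NULL))
  }
  per_part <- data[data$item == 1L, c("participant", "condition", "pretest")]
  per_cond <- tapply(data$condition, factor(data$participant, levels = ids),
                     function(x) length(unique(x)) == 1L)
  per_pre <- tapply(data$pretest, factor(data$participant, levels = ids),
                    function(x) length(unique(x)) == 1L)
  if (!all(unlist(per_cond)) || !all(unlist(per_pre))) {
    stop("condition and pretest must be constant within participant", call. = FALSE)
  }

  structure(list(
    data = data,
    level = to_mat("level"),
    correct = to_mat("correct"),
    confidence = to_mat("confidence"),
    condition = stats::setNames(per_part$condition, as.character(per_part$participant)),
    pretest = stats::setNames(per_part$pretest, as.character(per_part$participant)),
    participants = ids,
    n = n,
    T = T_len
  ), class = "process_dataset")
}

#' @export
print.process_dataset <- function(x, ...) {
  cat(sprintf("process_dataset: %d participants x %d items\n", x$n, x$T))
  cat(sprintf("  condition: %d performance, %d learning\n",
              sum(x$condition == 1), sum(x$condition == 0)))
  cat(sprintf("  pretest: mean %.3f, range [%.2f, %.2f]\n",
              mean(x$pretest), min(x$pretest), max(x$pretest)))
  invisible(x)
}

#' Read a process dataset from long-format CSV
#'
#' Reads the standard long CSV (one row per participant x item) and
#' validates it. Confidence is stored in the file on the raw 0--100 rating
#' scale and converted proportionally to 0--1 on load; difficulty levels are
#' kept as integers 1--7.
#'
#' @param path CSV file with header `participant,item,level,correct,
#'   confidence,condition,pretest`
#' @param schema optional named character vector remapping non-standard
#'   column names, e.g. `c(level = "difficulty")` if the file calls the
#'   level column "difficulty".
#' @param check_grid passed to [process_dataset()] (the 0--100 file scale
#'   must then sit on multiples of 10).
#' @return a [process_dataset()]
#' @export
load_dataset <- function(path, schema = NULL, check_grid = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (std in names(schema)) {
      if (!schema[[std]] %in% names(df)) {
        stop(sprintf("schema column '%s' not found in %s", schema[[std]], path))
      }
      names(df)[names(df) == schema[[std]]] <- std
    }
  }
  if (!"confidence" %in% names(df)) stop("missing columns: confidence")
  if (any(!is.finite(df$confidence) | df$confidence < 0 | df$confidence > 100)) {
    bad <- which(!is.finite(df$confidence) | df$confidence < 0 | df$confidence > 100)[1L]
    stop(sprintf("confidence outside [0,100] at row %d", bad))
  }
  df$confidence <- df$confidence / 100
  process_dataset(df, check_grid = check_grid)
}

#' Write a process dataset to the long CSV format
#'
#' Inverse of [load_dataset()]: confidence is written back on the 0--100
#' scale so that a write-then-read round trip reproduces the dataset
#' exactly.
#'
#' @param dataset a [process_dataset()]
#' @param path output CSV path
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "process_dataset"))
  out <- dataset$data
  out$confidence <- round(out$confidence * 100, 10)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Rescale difficulty levels to the unit interval
#'
#' Observed levels 1..7 are divided by 7 so the emission scale is
#' comparable with the other unit-scale variables; [unscale_levels()] is the
#' exact inverse on the grid \{1/7, ..., 1\}.
#'
#' @param levels integer levels in 1..7 (vector or matrix)
#' @return values on the grid \{1/7, 2/7, ..., 1\}
#' @export
scale_levels <- function(levels) levels / 7

#' @rdname scale_levels
#' @param y scaled values on the 1/7 grid
#' @export
unscale_levels <- function(y) as.integer(round(y * 7))

#' Accumulated (running-mean) covariate track
#'
#' The transition covariates "accumulated correctness" and "accumulated
#' confidence" at item j are running means of the per-item values. In
#' `inclusive` mode the window is items 1..j (so item j's own outcome is
#' part of the covariate for the transition into item j); in `lagged` mode
#' it is items 1..j-1 and the value at j = 1 is `NA` (transitions are only
#' defined from item 2 onward, so it is never consumed).
#'
#' @param values numeric vector (or participants x items matrix) with
#'   entries in \[0,1\]
#' @param mode `"inclusive"` (default) or `"lagged"`
#' @return running means, same shape as `values`
#' @export
accumulate <- function(values, mode = c("inclusive", "lagged")) {
  mode <- match.arg(mode)
  if (is.matrix(values)) {
    out <- t(apply(values, 1L, accumulate, mode = mode))
    dimnames(out) <- dimnames(values)
    return(out)
  }
  if (length(values) == 0L) stop("empty input")
  if (any(!is.finite(values) | values < 0 | values > 1)) {
    stop("values must lie in [0,1]")
  }
  inc <- cumsum(values) / seq_along(values)
  if (mode == "inclusive") inc else c(NA_real_, inc[-length(inc)])
}

# Canonical covariate orderings; interactions are products of their factors.
.init_cov_order <- c("d", "p", "dp")
.trans_cov_order <- c("d", "f", "r", "fr", "df", "dr", "dfr")

.cov_product <- function(name, env) {
  # name like "dfr" -> product of the single-letter factors d, f, r
  factors <- strsplit(name, "")[[1L]]
  Reduce(`*`, lapply(factors, function(f) env[[f]]))
}

#' Build design matrices for the initial-state and transition regressions
#'
#' Constructs, for every participant, the initial-state covariate row
#' `I = [1, d, p, dp]` (restricted to the model's covariate set) and the
#' per-item transition covariate rows `h_j = [1, d, f_j, r_j, f_j r_j, ...]`
#' where `r` and `f` are the accumulated correctness and confidence tracks.
#' Interactions are literal products and the column order is fixed
#' (`d, p, dp` for the initial model; `d, f, r, fr, df, dr, dfr` for
#' transitions), matching the reporting convention of the model ladder.
#'
#' @param dataset a [process_dataset()]
#' @param spec a [model_def()] naming the covariate sets
#' @param mode accumulation mode for `r` and `f`, see [accumulate()]
#' @return list with `I` (n x (1+q_I) matrix) and `H` (list over items
#'   `2..T` is populated; element j is the n x (1+q_h) matrix of `h_j`;
#'   element 1 is `NULL` since no transition leads into item 1)
#' @export
build_designs <- function(dataset, spec, mode = c("inclusive", "lagged")) {
  stopifnot(inherits(dataset, "process_dataset"))
  mode <- match.arg(mode)
  init_cov <- spec$init_covariates
  trans_cov <- spec$trans_covariates
  unknown <- setdiff(init_cov, .init_cov_order)
  if (length(unknown)) stop("unknown initial covariate: ", unknown[1L])
  unknown <- setdiff(trans_cov, .trans_cov_order)
  if (length(unknown)) stop("unknown transition covariate: ", unknown[1L])
  init_cov <- .init_cov_order[.init_cov_order %in% init_cov]
  trans_cov <- .trans_cov_order[.trans_cov_order %in% trans_cov]

  n <- dataset$n
  env_init <- list(d = dataset$condition, p = dataset$pretest)
  I <- matrix(1, nrow = n, ncol = 1L + length(init_cov),
              dimnames = list(NULL, c("(Intercept)", init_cov)))
  for (nm in init_cov) I[, nm] <- .cov_product(nm, env_init)

  r_track <- accumulate(dataset$correct, mode = mode)
  f_track <- accumulate(dataset$confidence, mode = mode)
  H <- vector("list", dataset$T)
  if (dataset$T >= 2L) {
    for (j in 2:dataset$T) {
      env_j <- list(d = dataset$condition, f = f_track[, j], r = r_track[, j])
      Hj <- matrix(1, nrow = n, ncol = 1L + length(trans_cov),
                   dimnames = list(NULL, c("(Intercept)", trans_cov)))
      for (nm in trans_cov) Hj[, nm] <- .cov_product(nm, env_j)
      H[[j]] <- Hj
    }
  }
  list(I = I, H = H)
}

#' Design row for one participant at one covariate setting
#'
#' Expands named base-covariate values (e.g. `d`, `p` or `d`, `f`, `r`)
#' into the full design row including intercept and the required product
#' interactions, in the canonical column order.
#'
#' @param values named list/vector of base covariate values
#' @param covariates character vector of covariate names the model uses
#'   (may include interaction names like `"fr"`, `"dfr"`)
#' @return named numeric vector `[1, covariates...]`
#' @export
design_row <- function(values, covariates) {
  values <- as.list(values)
  out <- c("(Intercept)" = 1)
  for (nm in covariates) {
    out[nm] <- .cov_product(nm, values)
  }
  out
}
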