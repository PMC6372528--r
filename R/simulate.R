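#' Configuration of the synthetic cohort generator
#'
#' The generator emulates a two-condition self-adapted test cohort with
#' the structure the analysis assumes: latent difficulty-preference states
#' evolving as a (possibly covariate-dependent) Markov chain, Gaussian
#' emissions on the scaled difficulty axis discretized to the seven
#' manifest levels, correctness driven by the chosen level's success
#' probability (with an optional pre-test ability shift on the logit
#' scale), and confidence linked to correctness by a linear-Gaussian
#' channel calibrated so the pooled confidence-correctness point-biserial
#' correlation is about 0.60.
#'
#' Defaults reproduce the reported study conditions: 583 participants, 40
#' items, Bernoulli(0.5) condition assignment, pre-test scores from a
#' truncated normal (mean 0.75, SD 0.16, range 0.22--1), intercept-only
#' generating HMM with emission means (0.19, 0.51, 0.86), SDs
#' (0.07, 0.12, 0.13), initial probabilities (0.36, 0.45, 0.19) and sticky
#' transition rows with diagonal (0.93, 0.92, 0.90), and per-level success
#' probabilities (92, 80, 68, 55, 41, 30, 16)%.
#'
#' @param n_participants cohort size
#' @param n_items items per participant
#' @param p_performance probability of assignment to the performance
#'   condition (`d = 1`)
#' @param pretest_mean,pretest_sd,pretest_range truncated-normal pre-test
#'   score distribution
#' @param params generating [hmm_params()]; covariate slopes in its
#'   transition block switch on history-dependent transitions
#' @param level_success success probability at each difficulty level 1..7
#' @param ability_slope logit-scale shift of the success probability per
#'   unit of (pretest - 0.75); 0 disables ability modulation
#' @param conf_base,conf_gain,conf_sd confidence channel:
#'   `confidence = clamp01(conf_base + conf_gain * correct + N(0, conf_sd))`
#'   rounded to the 0.1 rating grid
#' @param seed integer seed; mandatory, so every cohort is reproducible
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_participants = 583L,
                       n_items = 40L,
                       p_performance = 0.5,
                       pretest_mean = 0.75,
                       pretest_sd = 0.16,
                       pretest_range = c(0.22, 1),
                       params = NULL,
                       level_success = c(0.92, 0.80, 0.68, 0.55, 0.41, 0.30, 0.16),
                       ability_slope = 2,
                       conf_base = 0.40,
                       conf_gain = 0.35,
                       conf_sd = 0.23,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("sim_config requires an explicit seed")
  if (is.null(params)) params <- default_generating_params()
  stopifnot(inherits(params, "hmm_params"),
            length(level_success) == 7L,
            all(level_success >= 0 & level_success <= 1))
  structure(list(n_participants = as.integer(n_participants),
                 n_items = as.integer(n_items),
                 p_performance = p_performance,
                 pretest_mean = pretest_mean, pretest_sd = pretest_sd,
                 pretest_range = pretest_range,
                 params = params, level_success = level_success,
                 ability_slope = ability_slope,
                 conf_base = conf_base, conf_gain = conf_gain,
                 conf_sd = conf_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default generating parameters (intercept-only three-state model)
#'
#' Emission means (0.19, 0.51, 0.86) with SDs (0.07, 0.12, 0.13), initial
#' state probabilities (0.36, 0.45, 0.19), and sticky transition rows
#' (0.93, 0.05, 0.02) / (0.04, 0.92, 0.04) / (0.04, 0.06, 0.90).
#'
#' @return an [hmm_params()]
#' @export
default_generating_params <- function() {
  pi1 <- c(0.36, 0.45, 0.19)
  P <- rbind(c(0.93, 0.05, 0.02),
             c(0.04, 0.92, 0.04),
             c(0.04, 0.06, 0.90))
  trans <- array(0, c(1, 3, 3))
  for (l in 1:3) trans[1, , l] <- log(P[l, ]) - log(P[l, 1L])
  hmm_params(mu = c(0.19, 0.51, 0.86), sigma = c(0.07, 0.12, 0.13),
             init_coef = matrix(log(pi1) - log(pi1[1L]), 1),
             trans_coef = trans, ref = 1L)
}

# Truncated-normal draw by inverse CDF.
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Correctness channel of the generator
#'
#' Draws Bernoulli correctness for items at the given difficulty levels:
#' the per-level success probability, shifted on the logit scale by
#' `ability_slope * (pretest - 0.75)`.
#'
#' @param level integer difficulty levels 1..7 (vectorized)
#' @param pretest pre-test proportion correct (scalar or vector)
#' @param config a [sim_config()]
#' @return 0/1 vector of the same length as `level`
#' @export
draw_correctness <- function(level, pretest, config) {
  ls <- config$level_success[level]
  shift <- config$ability_slope * (pretest - 0.75)
  p <- ifelse(ls <= 0 | ls >= 1, ls, stats::plogis(stats::qlogis(ls) + shift))
  stats::rbinom(length(level), 1L, p)
}

.draw_confidence <- function(correct, config) {
  raw <- config$conf_base + config$conf_gain * correct +
    stats::rnorm(length(correct), 0, config$conf_sd)
  round(pmin(pmax(raw, 0), 1) * 10) / 10
}

#' Simulate one participant's test session
#'
#' Generates, item by item: the latent state (initial-state model at item
#' 1, transition model afterwards, with any transition covariates built
#' from the history through the previous item -- the causal information
#' set at transition time), the continuous emission rounded and clamped to
#' the 1/7 grid and mapped to a manifest level, Bernoulli correctness from
#' the level's success probability, and grid-rounded confidence. Uses the
#' current RNG state; seed control lives in [simulate_dataset()].
#'
#' @param config a [sim_config()]
#' @param condition 0/1 goal condition
#' @param pretest pre-test proportion correct
#' @return list with integer `level`, `correct`, numeric `confidence`,
#'   integer latent `states` (all length `n_items`)
#' @export
simulate_participant <- function(config, condition, pretest) {
  params <- config$params
  T_len <- config$n_items
  M <- params$M
  level <- integer(T_len); correct <- integer(T_len)
  confidence <- numeric(T_len); states <- integer(T_len)

  I <- design_row(list(d = condition, p = pretest), params$init_covariates)
  pi1 <- initial_probs(params, I)
  for (j in seq_len(T_len)) {
    if (j == 1L) {
      states[j] <- sample.int(M, 1L, prob = pi1)
    } else {
      hist_idx <- seq_len(j - 1L)
      h <- design_row(list(d = condition,
                           r = mean(correct[hist_idx]),
                           f = mean(confidence[hist_idx])),
                      params$trans_covariates)
      P <- transition_matrix(params, h)
      states[j] <- sample.int(M, 1L, prob = P[states[j - 1L], ])
    }
    y <- stats::rnorm(1L, params$mu[states[j]], params$sigma[states[j]])
    level[j] <- min(max(as.integer(round(y * 7)), 1L), 7L)
    correct[j] <- draw_correctness(level[j], pretest, config)
    confidence[j] <- .draw_confidence(correct[j], config)
  }
  list(level = level, correct = correct, confidence = confidence,
       states = states)
}

#' Simulate a full synthetic cohort
#'
#' Draws conditions and pre-test scores, simulates every participant with
#' [simulate_participant()], and returns the assembled
#' [process_dataset()] together with the true latent paths (for decoding
#' evaluation) and the config. Fully reproducible: the seed in the config
#' drives everything, and the caller's RNG state is restored on exit.
#'
#' @param config a [sim_config()]
#' @return list of class `sim_result` with `dataset`, `states`
#'   (participants x items), `config`
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n <- config$n_participants
  condition <- stats::rbinom(n, 1L, config$p_performance)
  pretest <- .rtruncnorm(n, config$pretest_mean, config$pretest_sd,
                         config$pretest_range[1L], config$pretest_range[2L])

  sims <- lapply(seq_len(n), function(i) {
    simulate_participant(config, condition[i], pretest[i])
  })
  T_len <- config$n_items
  long <- data.frame(
    participant = rep(seq_len(n), each = T_len),
    item = rep(seq_len(T_len), times = n),
    level = unlist(lapply(sims, `[[`, "level")),
    correct = unlist(lapply(sims, `[[`, "correct")),
    confidence = unlist(lapply(sims, `[[`, "confidence")),
    condition = rep(condition, each = T_len),
    pretest = rep(pretest, each = T_len)
  )
  states <- do.call(rbind, lapply(sims, `[[`, "states"))
  rownames(states) <- as.character(seq_len(n))
  structure(list(dataset = process_dataset(long),
                 states = states, config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result (seed %d):\n", x$config$seed))
  print(x$dataset)
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes the standard long CSV (see [write_dataset()]), a side-channel
#' CSV of the true latent states (`participant,item,state`), and the
#' config (seed included) as JSON.
#'
#' @param sim a `sim_result` from [simulate_dataset()]
#' @param data_csv,states_csv,config_json output paths (any may be `NULL`
#'   to skip)
#' @export
write_simulation <- function(sim, data_csv = NULL, states_csv = NULL,
                             config_json = NULL) {
  stopifnot(inherits(sim, "sim_result"))
  if (!is.null(data_csv)) write_dataset(sim$dataset, data_csv)
  if (!is.null(states_csv)) {
    n <- nrow(sim$states); T_len <- ncol(sim$states)
    utils::write.csv(data.frame(
      participant = rep(seq_len(n), each = T_len),
      item = rep(seq_len(T_len), times = n),
      state = as.vector(t(sim$states))
    ), states_csv, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(config_json)) {
    cfg <- unclass(sim$config)
    cfg$params <- .params_to_list(sim$config$params)
    jsonlite::write_json(cfg, config_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(sim)
}
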