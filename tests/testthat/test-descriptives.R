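test_that("choice distribution pools all items and ignores participant order", {
  df <- tiny_long(n = 2, T_len = 3)
  df$level <- c(1L, 1L, 1L, 1L, 1L, 1L)
  ds <- process_dataset(df, check_grid = FALSE)
  expect_equal(unname(choice_distribution(ds)), c(1, 0, 0, 0, 0, 0, 0))

  sim <- simulate_dataset(sim_config(n_participants = 50, n_items = 10, seed = 401))
  d1 <- choice_distribution(sim$dataset)
  expect_equal(sum(d1), 1)
  shuffled <- sim$dataset$data
  ord <- rev(unique(shuffled$participant))
  shuffled <- shuffled[order(match(shuffled$participant, ord), shuffled$item), ]
  d2 <- choice_distribution(process_dataset(shuffled, check_grid = FALSE))
  expect_equal(d1, d2)
})

test_that("the empirical choice mixture matches the generating emission model", {
  sim <- simulate_dataset(sim_config(seed = 402))
  # conditional on the true states, level frequencies must match the
  # discretized Gaussian emission distribution of each state
  cfg <- sim$config
  breaks <- c(-Inf, (seq_len(6) + 0.5) / 7, Inf)
  for (m in 1:3) {
    theo <- diff(pnorm(breaks, cfg$params$mu[m], cfg$params$sigma[m]))
    emp <- tabulate(sim$dataset$level[sim$states == m], 7)
    emp <- emp / sum(emp)
    expect_lt(max(abs(emp - theo)), 0.02)
  }
  # the pooled distribution keeps the low and mid modes of the mixture
  d <- choice_distribution(sim$dataset)
  expect_gt(d["1"], d["2"])  # mode at level 1
  expect_gt(d["4"], d["3"])  # local mode at level 4
  expect_gt(d["4"], d["5"])
})

test_that("up/down transition counts use strict level changes", {
  expect_equal(transition_counts(c(1, 2, 2, 1)), c(up = 1, down = 1))
  expect_equal(transition_counts(rep(4, 10)), c(up = 0, down = 0))
  expect_equal(transition_counts(1:7), c(up = 6, down = 0))
  lv <- matrix(c(1, 2, 2, 1, 7, 5, 5, 6), 2, 4, byrow = TRUE,
               dimnames = list(c("a", "b"), NULL))
  tc <- transition_counts(lv)
  expect_equal(tc$up, c(1, 1))
  expect_equal(tc$down, c(1, 1))
  expect_true(all(tc$up + tc$down <= 3))
})

test_that("frequent sequences rank exact matches with first-occurrence ties", {
  df <- tiny_long(n = 4, T_len = 3)
  df$level <- c(1L, 2L, 3L,  1L, 2L, 3L,  1L, 2L, 3L,  7L, 7L, 7L)
  ds <- process_dataset(df, check_grid = FALSE)
  fs <- frequent_sequences(ds, k = 2)
  all_rows <- fs[fs$group == "all", ]
  expect_equal(all_rows$sequence[1], "1-2-3")
  expect_equal(all_rows$count[1], 3L)
  expect_equal(all_rows$proportion[1], 0.75)
  expect_equal(all_rows$sequence[2], "7-7-7")

  # counts over all distinct sequences sum to the number of participants
  fs_all <- frequent_sequences(ds, k = 100)
  expect_equal(sum(fs_all$count[fs_all$group == "all"]), 4L)

  # sticky latent states make constant sequences dominate the top ranks
  sticky <- default_generating_params()
  sticky$trans_coef[1, , ] <- 0
  for (l in 1:3) {
    p <- rep(0.005, 3); p[l] <- 0.99
    sticky$trans_coef[1, , l] <- log(p) - log(p[1])
  }
  # put state means exactly on the level grid so sticky paths emit constants
  sticky$mu <- c(1, 4, 6) / 7
  sticky$sigma <- rep(0.02, 3)
  sim <- simulate_dataset(sim_config(n_participants = 80, n_items = 8,
                                     params = sticky, seed = 403))
  top <- frequent_sequences(sim$dataset, k = 3)
  top_all <- top[top$group == "all", ]
  is_constant <- vapply(strsplit(top_all$sequence, "-"),
                        function(s) length(unique(s)) == 1, logical(1))
  expect_true(all(is_constant))
})

test_that("association statistics recover designed correlation structure", {
  df <- tiny_long(n = 2, T_len = 4)
  df$correct <- rep(c(1L, 0L, 1L, 0L), 2)
  df$confidence <- rep(c(1, 0, 1, 0), 2)
  ds <- process_dataset(df, check_grid = FALSE)
  expect_equal(association_stats(ds)$confidence_correct, 1)

  df$confidence <- 0.5
  expect_error(association_stats(process_dataset(df, check_grid = FALSE)),
               "zero-variance")

  # independent channels: correlations near zero
  set.seed(404)
  n <- 200; T_len <- 20
  big <- data.frame(
    participant = rep(1:n, each = T_len), item = rep(1:T_len, n),
    level = sample(1:7, n * T_len, TRUE),
    correct = sample(0:1, n * T_len, TRUE),
    confidence = sample(seq(0, 1, 0.1), n * T_len, TRUE),
    condition = 0L, pretest = 0.75
  )
  a <- association_stats(process_dataset(big))
  expect_lt(abs(a$level_correct), 0.05)
  expect_lt(abs(a$confidence_correct), 0.05)
  expect_lt(abs(a$level_confidence), 0.05)

  # the calibrated generator hits the designed confidence-correctness link
  sim <- simulate_dataset(sim_config(seed = 405))
  stats <- association_stats(sim$dataset)
  expect_lt(abs(stats$confidence_correct - 0.60), 0.05)
  # and difficulty is negatively associated with success and confidence
  expect_lt(stats$level_correct, 0)
  expect_lt(stats$level_confidence, 0)
})

test_that("residual autocorrelation machinery matches a direct oracle", {
  # persistent choices: the demeaned-residual ACF must match the plain
  # per-participant ACF when no participant/item effects are injected
  set.seed(406)
  n <- 300; T_len <- 40; phi <- 0.44
  lev <- t(vapply(seq_len(n), function(i) {
    x <- as.numeric(stats::arima.sim(list(ar = phi), T_len, sd = 0.9))
    pmin(pmax(round(4 + x), 1), 7)
  }, numeric(T_len)))
  df <- data.frame(participant = rep(1:n, each = T_len),
                   item = rep(1:T_len, n),
                   level = as.integer(as.vector(t(lev))),
                   correct = 0L, confidence = 0.5,
                   condition = 0L, pretest = 0.75)
  ds <- process_dataset(df, check_grid = FALSE)
  got <- residual_acf(ds, max_lag = 2)
  oracle <- mean(apply(lev, 1, function(x) {
    stats::acf(x, lag.max = 1, plot = FALSE)$acf[2]
  }))
  expect_equal(unname(got$acf["lag1"]), oracle, tolerance = 0.02)
  # discretization attenuates but preserves strong first-order persistence
  expect_gt(got$acf["lag1"], 0.25)
  expect_gt(got$acf["lag1"], got$acf["lag2"])

  # white noise: average lag-1 ACF within sampling error of zero
  lev_wn <- matrix(sample(1:7, n * T_len, TRUE), n, T_len)
  df$level <- as.integer(as.vector(t(lev_wn)))
  wn <- residual_acf(process_dataset(df, check_grid = FALSE), max_lag = 1)
  expect_lt(abs(wn$acf["lag1"]), 2 / sqrt(n * T_len) + 0.03)
})

test_that("participant and item effects are removed before the ACF", {
  set.seed(407)
  n <- 200; T_len <- 30
  part_eff <- sample(-2:2, n, TRUE)
  item_eff <- round(1.5 * sin(seq_len(T_len) / 4))
  lev <- outer(part_eff, item_eff, "+") + 4 +
    matrix(sample(-1:1, n * T_len, TRUE), n, T_len)
  lev <- pmin(pmax(lev, 1), 7)
  df <- data.frame(participant = rep(1:n, each = T_len),
                   item = rep(1:T_len, n),
                   level = as.integer(as.vector(t(lev))),
                   correct = 0L, confidence = 0.5,
                   condition = 0L, pretest = 0.75)
  got <- residual_acf(process_dataset(df, check_grid = FALSE), max_lag = 1)
  # the shared item wave would induce spurious correlation; demeaning kills it
  expect_lt(abs(got$acf["lag1"]), 0.06)
})

test_that("constant sequences are excluded from the ACF with a warning", {
  df <- tiny_long(n = 2, T_len = 3)
  df$level <- c(4L, 4L, 4L, 1L, 5L, 2L)
  ds <- process_dataset(df, check_grid = FALSE)
  expect_warning(res <- residual_acf(ds, max_lag = 1), "excluded")
  expect_equal(res$n_used, 1)
  expect_equal(res$n_excluded, 1)
})

test_that("the bundled summary aggregates per-condition transition counts", {
  sim <- simulate_dataset(sim_config(n_participants = 60, n_items = 12, seed = 408))
  s <- sequence_summary(sim$dataset, k = 5, max_lag = 2)
  expect_equal(sum(s$choice_distribution), 1)
  tc <- transition_counts(sim$dataset$level)
  expect_equal(unname(s$transitions$performance["up"]),
               mean(tc$up[sim$dataset$condition == 1]))
  path <- withr::local_tempfile(fileext = ".json")
  write_summary(s, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$n, 60)
  expect_length(back$choice_distribution, 7)
})
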