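# Hand-built traces: K classes x windows, with controllable joint products.
fake_trace <- function(J, windows = seq(0.5, by = 0.5, length.out = ncol(J))) {
  list(gamma = J, r = J, J = J, windows = windows)
}

test_that("window schedules are cumulative prefixes clamped to the trial", {
  expect_equal(as.numeric(window_schedule()), seq(0.5, 4, by = 0.5))
  expect_equal(as.numeric(window_schedule(0.5, 3, 4)), c(0.5, 3.5, 4))  # clamped tail
  expect_equal(as.numeric(window_schedule(1, 0.7, 1)), 1)
  expect_error(window_schedule(5, 1, 4), "max_s")
})

test_that("probability ratios normalize to unit mean", {
  expect_equal(probability_ratio(c(2, 2, 2)), c(1, 1, 1))
  expect_equal(probability_ratio(c(3, 1, 1, 1)), c(2, 2/3, 2/3, 2/3))
  expect_error(probability_ratio(c(0, 0)), "all zero")
  expect_error(probability_ratio(c(1, -1)), "non-negative")
  set.seed(14)
  for (rep in 1:1000) {
    g <- stats::rexp(sample(2:12, 1))
    expect_equal(mean(probability_ratio(g)), 1, tolerance = 1e-12)
  }
})

test_that("the joint probability is the running product of ratio vectors", {
  stim <- stimulus_config(c(10, 12, 15))
  fs <- 128
  bank <- list(intra = reference_bank(stim, fs, 256), inter = vector("list", 3))
  set.seed(15)
  trial <- make_clean_trial(12, fs = fs, n_samples = 256) +
    0.5 * matrix(rnorm(8 * 256), 8)
  tr <- window_traces(trial, bank, window_schedule(0.5, 0.5, 2), fs)
  for (m in seq_along(tr$windows)) {
    expect_equal(tr$J[, m],
                 apply(tr$r[, seq_len(m), drop = FALSE], 1, prod),
                 tolerance = 0)  # exact: same arithmetic must reproduce
    expect_equal(tr$r[, m], probability_ratio(tr$gamma[, m]), tolerance = 1e-14)
  }
  # trace length bound
  expect_lte(length(tr$windows), 1 + floor((2 - 0.5) / 0.5))
})

test_that("the decoder stops immediately, late, or never as the trace dictates", {
  # immediate stop at the first window
  J <- cbind(c(5, 0.1, 0.1), c(6, 0.1, 0.1))
  d <- apply_threshold(fake_trace(J), threshold_schedule(1.5))
  expect_true(d$valid); expect_identical(d$class, 1L)
  expect_equal(d$time_s, 0.5); expect_identical(d$n_windows, 1L)

  # crossing only at the third window
  J2 <- cbind(c(1.2, 1, 0.8), c(1.4, 1, 0.6), c(2.1, 1, 0.4))
  d2 <- apply_threshold(fake_trace(J2), threshold_schedule(2))
  expect_identical(d2$n_windows, 3L)
  expect_equal(d2$time_s, 1.5)

  # exhaustion: invalid decision carries no class
  d3 <- apply_threshold(fake_trace(J2), threshold_schedule(50))
  expect_false(d3$valid)
  expect_true(is.na(d3$class))
  expect_equal(d3$time_s, 1.5)
})

test_that("a noise-free trial is decided early and correctly", {
  stim <- stimulus_config_12class()
  fs <- 128
  templates <- lapply(seq_len(stim$K), function(i)
    make_clean_trial(stim$frequencies[i], fs = fs, phase = stim$phases[i]))
  bank <- list(intra = templates, inter = vector("list", stim$K))
  trial <- make_clean_trial(stim$frequencies[5], fs = fs, phase = stim$phases[5])
  d <- decode_trial(trial, bank, window_schedule(), threshold_schedule(1.5), fs)
  expect_true(d$valid)
  expect_identical(d$class, 5L)
  expect_lte(d$time_s, 1)
})

test_that("decisions are monotone in the cut-off level", {
  set.seed(16)
  traces <- lapply(1:100, function(i)
    fake_trace(matrix(stats::rexp(4 * 8, rate = 1 / 1.2), 4, 8),
               windows = seq(0.5, 4, by = 0.5)))
  tc_lo <- threshold_schedule(c(1.2, 1.5, 2, 2.5))
  tc_hi <- threshold_schedule(c(1.4, 2.5, 3, 4))
  for (tr in traces) {
    t_lo <- apply_threshold(tr, tc_lo)$time_s
    t_hi <- apply_threshold(tr, tc_hi)$time_s
    expect_gte(t_hi, t_lo)
  }
})

test_that("cut-off 1 decides every trial at once; a huge cut-off never decides", {
  set.seed(17)
  traces <- lapply(1:20, function(i)
    fake_trace(matrix(stats::rexp(4 * 8), 4, 8), windows = seq(0.5, 4, 0.5)))
  for (tr in traces) {
    # per-window ratio vectors have unit mean, so the max is always >= 1
    r <- apply(tr$J, 2, function(x) x / mean(x))
    tr1 <- tr; tr1$J <- r
    expect_identical(apply_threshold(tr1, threshold_schedule(1))$n_windows, 1L)
    expect_false(apply_threshold(tr, threshold_schedule(1e12))$valid)
  }
})

test_that("grid search honors the strict 20% invalid-trial ceiling", {
  windows <- seq(0.5, 4, by = 0.5)
  # trial with a strong (correct) trace: max J = 10 from the first window
  strong <- function(label) {
    J <- matrix(0.5, 3, 8); J[label, ] <- 10
    fake_trace(J, windows)
  }
  # weak trial: never exceeds 1.9, and its argmax is wrong
  weak <- function(label) {
    J <- matrix(0.5, 3, 8); J[(label %% 3) + 1, ] <- 1.9
    fake_trace(J, windows)
  }
  # buckets below 3 s are pinned above the weak trials' reach, so only the
  # final bucket decides their fate: decide wrongly (1.5) or go invalid (5)
  grid21 <- structure(list(2, 2, 2, c(1.5, 5)), edges = c(1, 2, 3, 4))
  labels <- rep(1:3, length.out = 100)

  # 21 weak trials: the high cut-off leaves 21% invalid -> discarded, and the
  # search must settle on the permissive (lower-accuracy) schedule
  traces21 <- c(lapply(labels[1:79], strong), lapply(labels[80:100], weak))
  gs21 <- grid_search_threshold(traces21, labels, grid = grid21)
  expect_equal(gs21$schedule$values[4], 1.5)
  expect_equal(gs21$invalid, 0)
  expect_equal(gs21$accuracy, 0.79)

  # exactly 20 weak trials: 20% invalid is kept (strictly-greater rule), and
  # the high cut-off wins on accuracy
  traces20 <- c(lapply(labels[1:80], strong), lapply(labels[81:100], weak))
  gs20 <- grid_search_threshold(traces20, labels, grid = grid21)
  expect_equal(gs20$schedule$values[4], 5)
  expect_equal(gs20$invalid, 0.2)
  expect_equal(gs20$accuracy, 1)
})

test_that("a single-candidate grid is returned unchanged", {
  tr <- fake_trace(matrix(c(3, 1, 3, 1, 3, 1, 3, 1), 2, 4), c(1, 2, 3, 4))
  grid1 <- structure(list(1.2, 1.4, 1.6, 1.8), edges = c(1, 2, 3, 4))
  gs <- grid_search_threshold(list(tr), 1L, grid = grid1)
  expect_equal(gs$schedule$values, c(1.2, 1.4, 1.6, 1.8))
})

test_that("grid search falls back loudly when no candidate is feasible", {
  windows <- seq(0.5, 4, 0.5)
  dead <- fake_trace(matrix(1, 2, 8), windows)  # max J = 1 forever
  grid <- structure(list(2, 2, 2, c(2, 3)), edges = c(1, 2, 3, 4))
  expect_warning(gs <- grid_search_threshold(lapply(1:5, function(i) dead),
                                             rep(1L, 5), grid = grid),
                 "invalid-trial ceiling")
  expect_false(gs$log$feasible)
  expect_equal(gs$schedule$values, c(2, 2, 2, 3))
})

test_that("reported invalid proportions agree with a decision recount", {
  set.seed(18)
  windows <- seq(0.5, 4, 0.5)
  traces <- lapply(1:60, function(i)
    fake_trace(matrix(stats::rexp(4 * 8, 1 / 1.3), 4, 8), windows))
  labels <- sample(1:4, 60, replace = TRUE)
  gs <- suppressWarnings(grid_search_threshold(traces, labels))
  recount <- mean(!vapply(traces, function(tr)
    apply_threshold(tr, gs$schedule)$valid, logical(1)))
  expect_equal(gs$invalid, recount)
})

test_that("the default grid matches the published duration buckets", {
  g <- default_tc_grid()
  expect_equal(g[[1]], seq(1, 2, 0.05))
  expect_equal(g[[2]], seq(1, 4, 0.1))
  expect_equal(g[[3]], seq(3, 8, 0.2))
  expect_equal(g[[4]], seq(3, 16, 0.4))
  expect_equal(attr(g, "edges"), c(1, 2, 3, 4))
})
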