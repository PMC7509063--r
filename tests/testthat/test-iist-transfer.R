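test_that("intra_template is the element-wise mean of training trials", {
  a <- matrix(1, 2, 4); b <- matrix(3, 2, 4)
  expect_equal(unclass(intra_template(list(a, b)))[, ], matrix(2, 2, 4)[, ])
  single <- matrix(rnorm(8), 2, 4)
  expect_equal(intra_template(list(single)), single, ignore_attr = TRUE)
  expect_error(intra_template(list()), "non-empty")
  expect_error(intra_template(list(a, matrix(0, 3, 4))), "common shape")
})

test_that("template SNR grows with the number of averaged trials", {
  set.seed(20)
  sig <- make_clean_trial(10, n_channels = 2, amplitudes = 1)
  snr_of <- function(n) {
    trials <- lapply(seq_len(n), function(i) sig + matrix(rnorm(2 * 512), 2))
    tmpl <- intra_template(trials)
    mean(sig^2) / mean((tmpl - sig)^2)
  }
  snrs <- vapply(c(1, 4, 16), snr_of, numeric(1))
  expect_true(all(diff(snrs) > 0))
  # ~N-fold power growth: 16 trials should gain an order of magnitude over 1
  expect_gt(snrs[3] / snrs[1], 8)
})

test_that("confidence is the labeled score over the mean score", {
  expect_equal(ssvepmsi:::.confidence_from_scores(c(0.4, 0.4, 0.4), 2), 1)
  expect_equal(ssvepmsi:::.confidence_from_scores(c(2, 1), 1), 4 / 3)
  expect_error(ssvepmsi:::.confidence_from_scores(c(0, 0), 1), "degenerate")
  # scale invariance
  sc <- c(0.9, 0.2, 0.4, 0.1)
  expect_equal(ssvepmsi:::.confidence_from_scores(sc * 17, 1),
               ssvepmsi:::.confidence_from_scores(sc, 1))
})

test_that("a noise-free trial has confidence above 1 at its own label", {
  stim <- stimulus_config_12class()
  bank <- reference_bank(stim, 128, 512)
  tr <- make_clean_trial(stim$frequencies[4], phase = stim$phases[4])
  expect_gt(trial_confidence(tr, 4, bank), 1)
})

test_that("the confidence cut-off follows the window-seconds reading", {
  expect_equal(confidence_cutoff(512, 128), 1 + log(4))
  expect_equal(confidence_cutoff(128, 128), 1)
  # the product reading is available but far more conservative
  expect_gt(confidence_cutoff(512, 128, "product"), 10)
})

test_that("high-confidence selection keeps signal trials, drops noise trials", {
  set.seed(23)
  stim <- stimulus_config(c(10, 12, 15))
  bank <- reference_bank(stim, 128, 512)
  clean <- lapply(1:3, function(i) make_clean_trial(10, n_channels = 8) +
                    0.05 * matrix(rnorm(8 * 512), 8))
  noise <- lapply(1:3, function(i) matrix(rnorm(8 * 512), 8))
  keep <- select_high_confidence(c(clean, noise), 1, bank)
  expect_setequal(keep, 1:3)
  conf <- attr(keep, "confidence")
  expect_true(all(conf[1:3] > confidence_cutoff(512, 128)))
  expect_true(all(conf[4:6] < confidence_cutoff(512, 128)))
  # an empty selection is allowed
  expect_length(select_high_confidence(noise, 1, bank), 0L)
})

test_that("lapse trials are excluded from transfer at a higher rate", {
  spec <- synthetic_spec(n_subjects = 1, n_trials = 30, fs = 128,
                         subject_snr_db = -4, lapse_rate = 0.3, seed = 29)
  ds <- simulate_dataset(spec)
  bank <- reference_bank(ds$stim, 128, 512)
  excl_lapse <- 0; n_lapse <- 0; excl_clean <- 0; n_clean <- 0
  for (i in 1:4) {
    keep <- select_high_confidence(ds$epochs[[1]][[i]], i, bank)
    lp <- ds$lapse[[1]][i, ]
    n_lapse <- n_lapse + sum(lp); n_clean <- n_clean + sum(!lp)
    excl_lapse <- excl_lapse + sum(lp & !(seq_len(30) %in% keep))
    excl_clean <- excl_clean + sum(!lp & !(seq_len(30) %in% keep))
  }
  expect_gt(excl_lapse / n_lapse, excl_clean / n_clean)
})

test_that("inter_template is a two-stage average skipping empty donors", {
  a <- matrix(2, 2, 3); b <- matrix(6, 2, 3)
  # one donor, one trial
  expect_equal(inter_template(list(list(a))), a, ignore_attr = TRUE)
  # per-donor means first: donor weights are equal regardless of trial counts
  y <- inter_template(list(list(a, a, a), list(b)))
  expect_equal(y, (a + b) / 2, ignore_attr = TRUE)
  # empty donors are skipped, not zero-filled
  y2 <- inter_template(list(list(), list(b), list()))
  expect_equal(y2, b, ignore_attr = TRUE)
  expect_identical(attr(y2, "skipped"), c(1L, 3L))
  expect_null(inter_template(list(list(), list())))
})

test_that("opposite-phase donors interfere destructively in the template", {
  s1 <- make_clean_trial(10, n_channels = 2, amplitudes = 1, phase = 0)
  s2 <- make_clean_trial(10, n_channels = 2, amplitudes = 1, phase = pi)
  y <- inter_template(list(list(s1), list(s2)))
  expect_lt(mean(y^2), 0.01 * mean(s1^2))
})

test_that("donor selection ranks by accuracy with deterministic ties", {
  expect_identical(select_donors(c(90, 95, 80), 2), c(2L, 1L))
  expect_identical(select_donors(c(90, 95, 80), 0), integer(0))
  expect_identical(select_donors(c(50, 50, 40), 2), c(1L, 2L))  # tie -> lower index
  expect_warning(sel <- select_donors(c(90, 95), 5), "capping")
  expect_identical(sel, c(2L, 1L))
})

test_that("a pure-noise donor ranks last and is excluded", {
  spec <- synthetic_spec(n_subjects = 4, n_trials = 4, fs = 128, duration_s = 2,
                         subject_snr_db = c(0, 0, -60, 0), seed = 37)
  ds <- simulate_dataset(spec)
  acc <- vapply(1:4, msi_self_accuracy, numeric(1), dataset = ds)
  expect_identical(which.min(acc), 3L)
  expect_false(3L %in% select_donors(acc, 2))
})

test_that("gamma combines intra and inter synchrony as a sum of squares", {
  set.seed(41)
  ep <- matrix(rnorm(3 * 200), 3)
  intra <- list(matrix(rnorm(3 * 200), 3), matrix(rnorm(3 * 200), 3))
  inter <- list(matrix(rnorm(3 * 200), 3), NULL)
  bank <- list(intra = intra, inter = inter)
  res <- classify_iist(ep, bank)
  s1 <- synchronization_index(ep, intra[[1]])
  s1s <- synchronization_index(ep, inter[[1]])
  s2 <- synchronization_index(ep, intra[[2]])
  expect_equal(res$scores, c(s1^2 + s1s^2, s2^2), tolerance = 1e-12)
  expect_true(all(res$scores >= 0 & res$scores <= 2))
})

test_that("without inter templates the ranking reduces to intra-only MSI", {
  set.seed(43)
  ep <- matrix(rnorm(4 * 256), 4)
  intra <- lapply(1:5, function(i) matrix(rnorm(4 * 256), 4))
  bank0 <- list(intra = intra, inter = vector("list", 5))
  res <- classify_iist(ep, bank0)
  s <- vapply(intra, function(y) synchronization_index(ep, y), numeric(1))
  expect_identical(res$class, which.max(s))
  expect_equal(res$scores, s^2, tolerance = 1e-12)
})

test_that("with sine-cosine templates the decision equals plain MSI", {
  stim <- stimulus_config(c(10, 12, 15))
  bank <- reference_bank(stim, 128, 256)
  tb <- list(intra = bank, inter = bank)
  set.seed(47)
  for (rep in 1:5) {
    ep <- matrix(rnorm(4 * 256), 4)
    expect_identical(classify_iist(ep, tb)$class, classify_msi(ep, bank)$class)
  }
})

test_that("build_template_bank assembles templates with full provenance", {
  ds <- tiny_dataset()
  tb <- build_template_bank(ds, subject = 1, train_idx = 1:4, n_donors = 2)
  expect_s3_class(tb, "template_bank")
  expect_length(tb$intra, 12L)
  expect_length(tb$inter, 12L)
  expect_length(tb$provenance$donors, 2L)
  expect_false(1L %in% tb$provenance$donors)
  expect_equal(tb$provenance$cutoff, 1 + log(4))
  # intra template is the mean of the chosen training trials
  expect_equal(tb$intra[[3]],
               intra_template(ds$epochs[[1]][[3]][1:4]), tolerance = 1e-12)
})
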