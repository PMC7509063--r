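#' Cross-validated benchmark of SSVEP decoders
#'
#' Runs any subset of the decoders over a dataset with per-class k-fold
#' cross-validation and reports accuracy (mean of fold percentages over valid
#' trials), ITR, invalid proportion, and mean decision time per subject.
#'
#' Methods: `"cca"` (sine-cosine CCA), `"msi"` (sine-cosine MSI), `"mset"`
#' (multi-set CCA optimized references), `"itcca"` (individual-template CCA),
#' `"itmsi"` (individual-template MSI, i.e. the transfer decoder with an
#' empty donor set), `"iist"` (combined intra + inter template MSI), and
#' `"iist_at"` (the same with the dynamic-window adaptive threshold; its
#' cut-off schedule is grid-searched on the training folds of each subject).
#' Fixed-window methods are scored at every window length; `"iist_at"` is
#' scored once per subject, and its reported time is the mean decision time
#' of valid test trials.
#'
#' Templates, multi-set filters and cut-off schedules are always fitted on
#' training folds only; donor screening uses the donors' full data, which is
#' legitimate because donors are never test subjects.
#'
#' @param dataset an `ssvep_dataset`.
#' @param methods character vector, see above; default runs everything.
#' @param windows analysis window lengths in seconds (default 0.5 to 4 by
#'   0.5); also the dynamic-window schedule of `"iist_at"`.
#' @param n_donors donor set size `|P|` for the transfer templates (default 4).
#' @param n_folds cross-validation folds (default 3).
#' @param n_harmonics reference harmonics (default 3).
#' @param seed seed controlling the fold assignment.
#' @param tc_grid cut-off candidate grid for `"iist_at"` ([default_tc_grid()]).
#' @param max_invalid invalid-proportion ceiling in the grid search.
#' @param gaze_shift_s per-selection gaze-shift overhead added to the ITR's
#'   selection time (default 1 s).
#' @param itr_convention `"bits"` (default) or `"nat"`, see [itr()].
#' @return a `data.frame` with columns `subject`, `method`, `window_s`
#'   (`NA` for `"iist_at"`), `accuracy` (percent), `itr`, `invalid_prop`,
#'   `mean_decision_time_s`; attribute `at_schedules` holds the per-subject,
#'   per-fold grid-search results.
#' @export
run_benchmark <- function(dataset,
                          methods = c("cca", "msi", "mset", "itcca",
                                      "itmsi", "iist", "iist_at"),
                          windows = seq(0.5, 4, by = 0.5),
                          n_donors = 4L, n_folds = 3L, n_harmonics = 3L,
                          seed = 1L, tc_grid = default_tc_grid(),
                          max_invalid = 0.2, gaze_shift_s = 1,
                          itr_convention = c("bits", "nat")) {
  itr_convention <- match.arg(itr_convention)
  validate_dataset(dataset)
  methods <- match.arg(methods, several.ok = TRUE)
  fs <- dataset$fs
  stim <- dataset$stim
  K <- stim$K
  n_sub <- length(dataset$epochs)
  n_tr <- length(dataset$epochs[[1]][[1]])
  M <- ncol(dataset$epochs[[1]][[1]][[1]])
  win_samp <- pmin(M, as.integer(round(windows * fs)))
  n_win <- length(windows)

  transfer_needed <- any(c("iist", "iist_at") %in% methods) && n_donors > 0L
  intra_needed <- any(c("itcca", "itmsi", "iist", "iist_at") %in% methods)
  need_sine <- any(c("cca", "msi") %in% methods) || transfer_needed

  # sine-cosine reference preps, shared by every subject and fold
  ref_prep <- NULL
  if (need_sine) {
    bank_full <- reference_bank(stim, fs, M, n_harmonics)
    ref_prep <- lapply(win_samp, function(nw) {
      lapply(bank_full, function(y) .score_prep(y[, seq_len(nw), drop = FALSE]))
    })
  }

  # donor-side statistics (full-length, test-subject independent)
  donor_acc <- NULL
  donor_class_mean <- NULL
  if (transfer_needed) {
    bank_full <- reference_bank(stim, fs, M, n_harmonics)
    cutoff <- confidence_cutoff(M, fs)
    donor_acc <- vapply(seq_len(n_sub), msi_self_accuracy, numeric(1),
                        dataset = dataset, bank = bank_full)
    donor_class_mean <- lapply(seq_len(n_sub), function(p) {
      lapply(seq_len(K), function(i) {
        keep <- select_high_confidence(dataset$epochs[[p]][[i]], i, bank_full, cutoff)
        if (length(keep) == 0L) NULL else
          intra_template(dataset$epochs[[p]][[i]][keep])
      })
    })
  }

  fixed_methods <- setdiff(methods, "iist_at")
  rows <- list()
  at_schedules <- vector("list", n_sub)

  for (s in seq_len(n_sub)) {
    # inter-subject templates for this test subject
    inter <- vector("list", K)
    if (transfer_needed) {
      pool <- setdiff(seq_len(n_sub), s)
      donors <- pool[select_donors(donor_acc[pool], n_donors)]
      for (i in seq_len(K)) {
        means <- Filter(Negate(is.null), lapply(donors, function(p) donor_class_mean[[p]][[i]]))
        if (length(means)) inter[[i]] <- Reduce(`+`, means) / length(means)
      }
    }
    prep_inter <- lapply(seq_len(n_win), function(w) {
      lapply(inter, function(y) {
        if (is.null(y)) NULL else .score_prep(y[, seq_len(win_samp[w]), drop = FALSE])
      })
    })

    plan <- cv_plan(K, n_tr, n_folds, seed = seed + s)
    # per-fold tallies: correct[method, window, fold]; AT counters
    correct <- array(0L, dim = c(length(fixed_methods), n_win, n_folds),
                     dimnames = list(fixed_methods, NULL, NULL))
    n_test <- integer(n_folds)
    at_correct <- integer(n_folds); at_valid <- integer(n_folds)
    at_total <- integer(n_folds); at_times <- numeric(0)
    at_schedules[[s]] <- vector("list", n_folds)

    for (f in seq_len(n_folds)) {
      train_idx <- lapply(seq_len(K), function(i) which(plan[i, ] != f))
      test_idx <- lapply(seq_len(K), function(i) which(plan[i, ] == f))

      prep_intra <- NULL; intra <- NULL
      if (intra_needed) {
        intra <- lapply(seq_len(K), function(i) {
          intra_template(dataset$epochs[[s]][[i]][train_idx[[i]]])
        })
        prep_intra <- lapply(seq_len(n_win), function(w) {
          lapply(intra, function(y) .score_prep(y[, seq_len(win_samp[w]), drop = FALSE]))
        })
      }
      prep_zn <- NULL
      if ("mset" %in% methods) {
        zn <- lapply(seq_len(K), function(i) {
          fit_mset_cca(dataset$epochs[[s]][[i]][train_idx[[i]]])$reference
        })
        prep_zn <- lapply(seq_len(n_win), function(w) {
          lapply(zn, function(y) .score_prep(y[, seq_len(win_samp[w]), drop = FALSE]))
        })
      }

      need_at <- "iist_at" %in% methods
      # score one trial at every window; returns per-method predictions and
      # the gamma trace used by the adaptive decoder
      score_trial <- function(trial, want_fixed) {
        preds <- if (want_fixed)
          matrix(NA_integer_, length(fixed_methods), n_win,
                 dimnames = list(fixed_methods, NULL)) else NULL
        gam <- if (need_at) matrix(NA_real_, K, n_win) else NULL
        for (w in seq_len(n_win)) {
          px <- .score_prep(trial[, seq_len(win_samp[w]), drop = FALSE])
          s_intra <- NULL; s_inter <- NULL
          if (intra_needed && (need_at || want_fixed)) {
            if (any(c("itmsi", "iist", "iist_at") %in% methods)) {
              s_intra <- vapply(seq_len(K), function(i)
                .msi_from_prep(px, prep_intra[[w]][[i]]), numeric(1))
            }
            if (transfer_needed) {
              s_inter <- vapply(seq_len(K), function(i) {
                if (is.null(prep_inter[[w]][[i]])) 0 else
                  .msi_from_prep(px, prep_inter[[w]][[i]])
              }, numeric(1))
            }
          }
          if (want_fixed) {
            for (m in fixed_methods) {
              sc <- switch(m,
                cca   = vapply(ref_prep[[w]], function(py) .cca_rho_from_prep(px, py), numeric(1)),
                msi   = vapply(ref_prep[[w]], function(py) .msi_from_prep(px, py), numeric(1)),
                mset  = vapply(prep_zn[[w]], function(py) .cca_rho_from_prep(px, py), numeric(1)),
                itcca = vapply(prep_intra[[w]], function(py) .cca_rho_from_prep(px, py), numeric(1)),
                itmsi = s_intra^2,
                iist  = s_intra^2 + (if (is.null(s_inter)) 0 else s_inter^2))
              preds[m, w] <- which.max(sc)
            }
          }
          if (need_at) {
            gam[, w] <- s_intra^2 + (if (is.null(s_inter)) 0 else s_inter^2)
          }
        }
        list(preds = preds, gamma = gam)
      }

      gamma_to_trace <- function(gam) {
        r <- apply(gam, 2, probability_ratio)
        if (n_win == 1L) r <- matrix(r, ncol = 1L)
        J <- t(apply(r, 1, cumprod))
        if (n_win == 1L) J <- matrix(J, ncol = 1L)
        list(gamma = gam, r = r, J = J, windows = windows)
      }

      # gamma trace of a training trial with its own class template rebuilt
      # without the trial (leave-one-out): scoring a trial against a template
      # it was averaged into saturates the training accuracy and would let
      # the decision-time tie-break pick overly aggressive cut-offs
      trace_train_trial <- function(trial, label) {
        n_i <- length(train_idx[[label]])
        loo <- if (n_i > 1L) {
          (n_i * intra[[label]] - trial) / (n_i - 1L)
        } else {
          intra[[label]]
        }
        gam <- matrix(NA_real_, K, n_win)
        for (w in seq_len(n_win)) {
          px <- .score_prep(trial[, seq_len(win_samp[w]), drop = FALSE])
          s_intra <- vapply(seq_len(K), function(i) {
            py <- if (i == label) .score_prep(loo[, seq_len(win_samp[w]), drop = FALSE])
                  else prep_intra[[w]][[i]]
            .msi_from_prep(px, py)
          }, numeric(1))
          g <- s_intra^2
          if (transfer_needed) {
            g <- g + vapply(seq_len(K), function(i) {
              if (is.null(prep_inter[[w]][[i]])) 0 else
                .msi_from_prep(px, prep_inter[[w]][[i]])
            }, numeric(1))^2
          }
          gam[, w] <- g
        }
        gam
      }

      # training traces for the cut-off grid search
      at_eval <- NULL
      if (need_at) {
        tr_traces <- list(); tr_labels <- integer(0)
        for (i in seq_len(K)) {
          for (h in train_idx[[i]]) {
            gam <- trace_train_trial(dataset$epochs[[s]][[i]][[h]], i)
            tr_traces[[length(tr_traces) + 1L]] <- gamma_to_trace(gam)
            tr_labels <- c(tr_labels, i)
          }
        }
        at_eval <- grid_search_threshold(tr_traces, tr_labels, grid = tc_grid,
                                         max_invalid = max_invalid)
        at_schedules[[s]][[f]] <- at_eval
      }

      # test trials
      te_traces <- list(); te_labels <- integer(0)
      for (i in seq_len(K)) {
        for (h in test_idx[[i]]) {
          sc <- score_trial(dataset$epochs[[s]][[i]][[h]],
                            want_fixed = length(fixed_methods) > 0L)
          if (!is.null(sc$preds)) {
            n_test[f] <- n_test[f] + 1L
            correct[, , f] <- correct[, , f] + (sc$preds == i)
          }
          if (need_at) {
            te_traces[[length(te_traces) + 1L]] <- gamma_to_trace(sc$gamma)
            te_labels <- c(te_labels, i)
          }
        }
      }
      if (need_at) {
        pk <- .pack_traces(te_traces)
        cut <- .tc_for_windows(at_eval$schedule$values, windows, at_eval$schedule$edges)
        ev <- .evaluate_schedule(pk$maxJ, pk$pred, windows, cut, te_labels)
        at_total[f] <- length(te_labels)
        at_valid[f] <- sum(ev$valid)
        at_correct[f] <- sum(ev$class[ev$valid] == te_labels[ev$valid])
        at_times <- c(at_times, ev$time_s[ev$valid])
      }
    }

    for (m in fixed_methods) {
      for (w in seq_len(n_win)) {
        acc <- cv_accuracy(correct[m, w, ], n_test)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, method = m, window_s = windows[w], accuracy = acc,
          itr = itr(acc / 100, K, windows[w] + gaze_shift_s, itr_convention),
          invalid_prop = 0, mean_decision_time_s = windows[w])
      }
    }
    if ("iist_at" %in% methods) {
      acc <- cv_accuracy(at_correct, at_valid)
      mean_time <- if (length(at_times)) mean(at_times) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, method = "iist_at", window_s = NA_real_, accuracy = acc,
        itr = if (is.na(mean_time)) NA_real_ else
          itr(acc / 100, K, mean_time + gaze_shift_s, itr_convention),
        invalid_prop = 1 - sum(at_valid) / sum(at_total),
        mean_decision_time_s = mean_time)
    }
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "at_schedules") <- at_schedules
  attr(out, "itr_convention") <- itr_convention
  class(out) <- c("benchmark_result", "data.frame")
  out
}
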