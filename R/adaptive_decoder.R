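#' Dynamic-window schedule
#'
#' Cumulative prefix windows: the first decision is attempted at `itw_s`
#' seconds and each further attempt appends `twi_s` seconds, up to the trial
#' length `max_s` (the final window is clamped to `max_s` when the increment
#' overshoots).
#'
#' @param itw_s initial window length in seconds (default 0.5).
#' @param twi_s window increment in seconds (default 0.5).
#' @param max_s trial length in seconds (default 4).
#' @return numeric vector of window lengths (class `window_schedule`).
#' @export
window_schedule <- function(itw_s = 0.5, twi_s = 0.5, max_s = 4) {
  .assert_scalar_num(itw_s, "itw_s"); .assert_scalar_num(twi_s, "twi_s")
  .assert_scalar_num(max_s, "max_s")
  if (itw_s > max_s) stop("`itw_s` must not exceed `max_s`", call. = FALSE)
  w <- seq(itw_s, max_s, by = twi_s)
  if (max(w) < max_s - 1e-9) w <- c(w, max_s)  # clamp: last window is the full trial
  structure(w, class = "window_schedule")
}

#' Default cut-off grid, bucketed by decision duration
#'
#' Candidate cut-off values `T_c` depend on how much data has been seen:
#' durations up to 1 s search 1 to 2 by 0.05; 1-2 s search 1 to 4 by 0.1;
#' 2-3 s search 3 to 8 by 0.2; 3-4 s search 3 to 16 by 0.4. Longer windows
#' admit larger cut-offs because the joint probability is a growing product.
#'
#' @return list of four numeric candidate vectors with attribute `edges`
#'   (upper bucket edges in seconds).
#' @export
default_tc_grid <- function() {
  structure(list(seq(1, 2, by = 0.05),
                 seq(1, 4, by = 0.1),
                 seq(3, 8, by = 0.2),
                 seq(3, 16, by = 0.4)),
            edges = c(1, 2, 3, 4))
}

# Map per-bucket cut-off values to a per-window cut-off vector.
.tc_for_windows <- function(tc_values, windows, edges = c(1, 2, 3, 4)) {
  stopifnot(length(tc_values) == length(edges))
  idx <- findInterval(windows - 1e-9, edges) + 1L   # d <= edge -> bucket
  if (any(idx > length(edges))) stop("window length beyond the threshold schedule", call. = FALSE)
  tc_values[idx]
}

#' Threshold schedule mapping window lengths to cut-offs
#'
#' Either one cut-off per duration bucket (the default, matching the bucketed
#' search grid) or a single constant cut-off for every window.
#'
#' @param values numeric: length 4 (per bucket, upper edges 1/2/3/4 s) or
#'   length 1 (constant mode).
#' @param edges upper bucket edges in seconds (default `c(1, 2, 3, 4)`).
#' @return object of class `threshold_schedule`.
#' @export
threshold_schedule <- function(values, edges = c(1, 2, 3, 4)) {
  values <- as.numeric(values)
  if (length(values) == 1L) values <- rep(values, length(edges))
  if (length(values) != length(edges)) {
    stop("`values` must have one entry per bucket (or length 1)", call. = FALSE)
  }
  if (any(values < 1)) stop("cut-off values must be >= 1", call. = FALSE)
  structure(list(values = values, edges = edges), class = "threshold_schedule")
}

#' Per-window probability ratio of the class scores
#'
#' Each class score is divided by the mean score over classes, so the ratios
#' average to exactly 1 and express how much a class stands out in the
#' current window.
#'
#' @param gamma numeric vector of `K` non-negative scores, not all zero.
#' @return length-`K` ratio vector with `mean(r) == 1`.
#' @export
probability_ratio <- function(gamma) {
  if (any(!is.finite(gamma)) || any(gamma < 0)) {
    stop("scores must be finite and non-negative", call. = FALSE)
  }
  m <- mean(gamma)
  if (m == 0) stop("degenerate score vector: all zero", call. = FALSE)
  gamma / m
}

#' Score every window of a trial (decision-rule-independent trace)
#'
#' Computes, for each cumulative prefix of the trial, the per-class combined
#' template score, its probability ratio, and the running element-wise
#' product of ratios (the joint probability). The trace is independent of the
#' cut-off schedule, so threshold search can replay it cheaply.
#'
#' @param trial channels x samples epoch.
#' @param bank a [build_template_bank()] (templates are truncated to each
#'   prefix; they are built once at full length).
#' @param windows a [window_schedule()].
#' @param fs sampling rate in Hz.
#' @return `list(gamma, r, J, windows)`: three `K x n_windows` matrices and
#'   the window lengths.
#' @export
window_traces <- function(trial, bank, windows, fs) {
  trial <- as.matrix(trial)
  n_win <- length(windows)
  K <- length(bank$intra)
  gamma <- matrix(NA_real_, K, n_win)
  for (m in seq_len(n_win)) {
    n_samp <- min(ncol(trial), as.integer(round(windows[m] * fs)))
    gamma[, m] <- classify_iist(trial[, seq_len(n_samp), drop = FALSE], bank)$scores
  }
  r <- apply(gamma, 2, probability_ratio)
  J <- t(apply(r, 1, cumprod))
  if (n_win == 1L) { r <- matrix(r, ncol = 1L); J <- matrix(J, ncol = 1L) }
  list(gamma = gamma, r = r, J = J, windows = as.numeric(windows))
}

#' Apply a cut-off schedule to a precomputed trace
#'
#' Walks the windows in order; at the first window whose maximum joint
#' probability reaches the cut-off for that duration, the trial is decided as
#' the argmax class (ties to the lowest index). If the data are exhausted
#' with the maximum still below the cut-off, the trial is invalid.
#'
#' @param trace a [window_traces()] result.
#' @param tc a [threshold_schedule()] (or numeric accepted by it).
#' @return object of class `ssvep_decision`: `list(class, valid, time_s,
#'   n_windows, trace)`; `class` is `NA` iff `valid` is `FALSE`.
#' @export
apply_threshold <- function(trace, tc) {
  if (!inherits(tc, "threshold_schedule")) tc <- threshold_schedule(tc)
  cut <- .tc_for_windows(tc$values, trace$windows, tc$edges)
  maxJ <- apply(trace$J, 2, max)
  hit <- which(maxJ >= cut)
  if (length(hit) == 0L) {
    out <- list(class = NA_integer_, valid = FALSE,
                time_s = trace$windows[length(trace$windows)],
                n_windows = length(trace$windows), trace = trace)
  } else {
    m <- hit[1]
    out <- list(class = which.max(trace$J[, m]), valid = TRUE,
                time_s = trace$windows[m], n_windows = m, trace = trace)
  }
  structure(out, class = "ssvep_decision")
}

#' @export
print.ssvep_decision <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("<decision> class %d at %.2f s (%d windows)\n",
                x$class, x$time_s, x$n_windows))
  } else {
    cat(sprintf("<decision> invalid after %.2f s (%d windows)\n",
                x$time_s, x$n_windows))
  }
  invisible(x)
}

#' Decode one trial with the dynamic-window adaptive threshold
#'
#' Convenience wrapper: [window_traces()] then [apply_threshold()]. The bank
#' must come from training data excluding this trial's fold.
#'
#' @inheritParams window_traces
#' @param tc a [threshold_schedule()].
#' @return an `ssvep_decision` with the full score trace attached.
#' @export
decode_trial <- function(trial, bank, windows, tc, fs) {
  apply_threshold(window_traces(trial, bank, windows, fs), tc)
}

# Fast vectorized evaluation of one candidate schedule over many traces.
# traces: list of window_traces(); labels: integer truth. Returns accuracy on
# valid trials, invalid proportion, mean decision time (valid trials), and
# the per-trial decisions.
.evaluate_schedule <- function(maxJ, pred, windows, cut, labels) {
  n <- nrow(maxJ)
  hit <- maxJ >= matrix(cut, n, length(cut), byrow = TRUE)
  first <- ifelse(rowSums(hit) > 0L, max.col(hit, ties.method = "first"), NA_integer_)
  valid <- !is.na(first)
  cls <- rep(NA_integer_, n)
  cls[valid] <- pred[cbind(which(valid), first[valid])]
  times <- rep(windows[length(windows)], n)
  times[valid] <- windows[first[valid]]
  acc <- if (any(valid)) mean(cls[valid] == labels[valid]) else NA_real_
  list(accuracy = acc, invalid = mean(!valid),
       mean_time = if (any(valid)) mean(times[valid]) else NA_real_,
       class = cls, valid = valid, time_s = times)
}

# Pack traces into the matrices .evaluate_schedule consumes.
.pack_traces <- function(traces) {
  windows <- traces[[1]]$windows
  maxJ <- t(vapply(traces, function(tr) apply(tr$J, 2, max), numeric(length(windows))))
  pred <- t(vapply(traces, function(tr) apply(tr$J, 2, which.max), integer(length(windows))))
  list(maxJ = maxJ, pred = pred, windows = windows)
}

#' Grid search of the cut-off schedule on training traces
#'
#' Searches per-bucket cut-off values over the bucketed grid. Candidates whose
#' invalid-trial proportion exceeds `max_invalid` strictly are discarded;
#' among survivors the training accuracy (on valid trials) is maximized, ties
#' broken by shorter mean decision time, then by smaller cut-off values. The
#' default `"greedy"` mode starts from the most conservative schedule (bucket
#' maxima) and optimizes buckets in order of increasing duration; `"full"`
#' enumerates the whole product grid (slow; small grids only).
#'
#' @param traces list of [window_traces()] for the training trials.
#' @param labels integer vector of true classes, one per trace.
#' @param grid candidate list as [default_tc_grid()].
#' @param max_invalid invalid-proportion ceiling (default 0.2; the boundary
#'   itself is kept, only strictly larger proportions are discarded).
#' @param mode `"greedy"` (default) or `"full"`.
#' @return `list(schedule, accuracy, invalid, mean_time, log)`; `schedule` is
#'   a [threshold_schedule()]. If every candidate violates the invalid
#'   ceiling, the most conservative (largest) schedule is returned with a
#'   warning and `feasible = FALSE` in the log.
#' @export
grid_search_threshold <- function(traces, labels, grid = default_tc_grid(),
                                  max_invalid = 0.2, mode = c("greedy", "full")) {
  mode <- match.arg(mode)
  stopifnot(length(traces) == length(labels))
  edges <- attr(grid, "edges") %||% c(1, 2, 3, 4)
  pk <- .pack_traces(traces)
  eval_values <- function(vals) {
    cut <- .tc_for_windows(vals, pk$windows, edges)
    .evaluate_schedule(pk$maxJ, pk$pred, pk$windows, cut, labels)
  }
  better <- function(a, b) {
    # is candidate a strictly better than incumbent b?
    if (is.null(b)) return(TRUE)
    if (is.na(a$accuracy)) return(FALSE)
    if (is.na(b$accuracy)) return(TRUE)
    if (a$accuracy != b$accuracy) return(a$accuracy > b$accuracy)
    if (a$mean_time != b$mean_time) return(a$mean_time < b$mean_time)
    sum(a$values) < sum(b$values)
  }
  log <- list()
  if (mode == "full") {
    combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
    best <- NULL
    for (ri in seq_len(nrow(combos))) {
      vals <- as.numeric(combos[ri, ])
      ev <- eval_values(vals); ev$values <- vals
      feasible <- ev$invalid <= max_invalid
      log[[length(log) + 1L]] <- c(vals, accuracy = ev$accuracy,
                                   invalid = ev$invalid, feasible = feasible)
      if (feasible && better(ev, best)) best <- ev
    }
  } else {
    # coordinate ascent over buckets, earlier durations first, repeated until
    # stable; run from both the most conservative and the most permissive
    # corner of the grid, since the feasibility ceiling can strand a single
    # descent in a poor basin. The best feasible candidate ever evaluated is
    # returned.
    best <- NULL
    for (start in list(vapply(grid, max, numeric(1)),
                       vapply(grid, min, numeric(1)))) {
      current <- start
      for (pass in 1:5) {
        moved <- FALSE
        for (b in seq_along(grid)) {
          best_b <- NULL
          for (cand in grid[[b]]) {
            vals <- current; vals[b] <- cand
            ev <- eval_values(vals); ev$values <- vals
            feasible <- ev$invalid <= max_invalid
            log[[length(log) + 1L]] <- c(pass = pass, bucket = b, tc = cand,
                                         accuracy = ev$accuracy,
                                         invalid = ev$invalid, feasible = feasible)
            if (feasible && better(ev, best_b)) best_b <- ev
            if (feasible && better(ev, best)) best <- ev
          }
          if (!is.null(best_b) && !identical(best_b$values, current)) {
            current <- best_b$values
            moved <- TRUE
          }
        }
        if (!moved) break
      }
    }
  }
  if (is.null(best)) {
    warning("every candidate schedule exceeded the invalid-trial ceiling; ",
            "falling back to the most conservative schedule", call. = FALSE)
    vals <- vapply(grid, max, numeric(1))
    best <- eval_values(vals); best$values <- vals
    feasible <- FALSE
  } else {
    feasible <- TRUE
  }
  list(schedule = threshold_schedule(best$values, edges),
       accuracy = best$accuracy, invalid = best$invalid,
       mean_time = best$mean_time,
       log = list(entries = log, feasible = feasible))
}
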