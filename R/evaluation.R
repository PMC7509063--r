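#' Per-class cross-validation fold assignment
#'
#' Randomly partitions each class's trials into `n_folds` folds of (near-)
#' equal size, independently per class, reproducibly from the seed. With 15
#' trials and 3 folds every fold holds 5 trials per class.
#'
#' @param n_classes number of stimulus classes.
#' @param n_trials trials per class.
#' @param n_folds folds (default 3).
#' @param seed integer seed.
#' @return `n_classes x n_trials` integer matrix of fold ids in `1..n_folds`.
#' @export
cv_plan <- function(n_classes, n_trials, n_folds = 3L, seed = 1L) {
  if (n_folds < 2L || n_folds > n_trials) {
    stop("`n_folds` must be between 2 and `n_trials`", call. = FALSE)
  }
  base <- rep_len(seq_len(n_folds), n_trials)
  with_seed(seed, {
    t(vapply(seq_len(n_classes), function(i) sample(base), integer(n_trials)))
  })
}

#' Cross-validated accuracy as a mean of fold percentages
#'
#' `acc = (1/F) * sum_i (P_i / N_i) * 100` with `P_i` the correctly classified
#' valid trials and `N_i` the valid trials of fold `i`. This is the unweighted
#' mean of fold-wise percentages, deliberately not the pooled ratio: the two
#' differ whenever invalid-trial filtering unbalances the folds. Folds with
#' `N_i = 0` are skipped with a warning.
#'
#' @param correct integer vector of per-fold correct counts.
#' @param valid integer vector of per-fold valid counts.
#' @return accuracy as a percentage in `[0, 100]`.
#' @examples
#' cv_accuracy(c(30, 60, 60), c(60, 60, 60))  # 83.33
#' @export
cv_accuracy <- function(correct, valid) {
  stopifnot(length(correct) == length(valid))
  if (any(correct > valid)) stop("`correct` cannot exceed `valid`", call. = FALSE)
  keep <- valid >= 1
  if (!any(keep)) stop("no fold has a valid trial", call. = FALSE)
  if (!all(keep)) warning("skipping fold(s) without valid trials", call. = FALSE)
  mean(correct[keep] / valid[keep]) * 100
}

#' Information transfer rate per minute
#'
#' Wolpaw's ITR: `B = log N + P log P + (1 - P) log((1 - P)/(N - 1))` bits per
#' selection, scaled by `60 / T` selections per minute. `convention = "bits"`
#' (the default) evaluates the logarithms base 2, the textbook unit;
#' `convention = "nat"` uses natural logarithms, a convention found in parts
#' of the SSVEP literature (the two differ by the factor `ln 2`). Below-chance
#' accuracies clamp `B` at 0 with a warning; `0 log 0 = 0` at `P` of 0 or 1.
#'
#' @param p accuracy as a fraction in `[0, 1]` (vectorized).
#' @param n_classes number of selectable targets, `N >= 2`.
#' @param t_s seconds per selection (analysis window plus gaze-shift time).
#' @param convention `"bits"` or `"nat"`.
#' @return ITR per minute (bits/min under `"bits"`).
#' @examples
#' itr(1, 12, 5)                       # 43.02 bits/min
#' itr(1, 12, 5, convention = "nat")   # 29.82 nat-based units
#' @export
itr <- function(p, n_classes, t_s, convention = c("bits", "nat")) {
  convention <- match.arg(convention)
  if (any(p < 0 | p > 1)) stop("`p` must be in [0, 1]", call. = FALSE)
  .assert_scalar_num(n_classes, "n_classes")
  if (n_classes < 2) stop("`n_classes` must be at least 2", call. = FALSE)
  .assert_scalar_num(t_s, "t_s")
  lg <- if (convention == "bits") log2 else log
  xlx <- function(x) ifelse(x > 0, x * lg(x), 0)
  b <- lg(n_classes) + xlx(p) + ifelse(p < 1, (1 - p) * lg((1 - p) / (n_classes - 1)), 0)
  below <- p < 1 / n_classes
  if (any(below)) {
    # Wolpaw's B turns positive again as P -> 0 (a perfectly *anti*-accurate
    # classifier is informative in theory, not in a BCI), so below-chance
    # accuracies are forced to zero rather than merely floored
    warning("below-chance accuracy: bit rate clamped at 0", call. = FALSE)
    b[below] <- 0
  }
  b <- pmax(b, 0)
  b * 60 / t_s
}

#' Band-pass filter and crop raw epochs
#'
#' Standard SSVEP preprocessing: a zero-phase (forward-backward) Butterworth
#' band-pass, default order 4 and 6-80 Hz, followed by cropping to the
#' stimulation segment (default 0.15-4.15 s, i.e. exactly 4 s of data once
#' the 0.15 s stimulus onset delay is dropped).
#'
#' @param x channels x samples matrix of one raw epoch, time starting at 0.
#' @param fs sampling rate in Hz; must exceed twice the upper band edge.
#' @param band lower/upper pass-band edges in Hz (default `c(6, 80)`).
#' @param order Butterworth order (default 4).
#' @param crop_s two-element crop window in seconds (default `c(0.15, 4.15)`);
#'   `NULL` to skip cropping.
#' @return the filtered (and cropped) matrix.
#' @export
preprocess_epoch <- function(x, fs, band = c(6, 80), order = 4L,
                             crop_s = c(0.15, 4.15)) {
  x <- as.matrix(x)
  if (fs <= 2 * band[2]) {
    stop(sprintf("upper band edge %g Hz at or above Nyquist for fs = %g Hz",
                 band[2], fs), call. = FALSE)
  }
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  out <- t(apply(x, 1, function(ch) signal::filtfilt(bf, ch)))
  if (!is.null(crop_s)) {
    idx <- (floor(crop_s[1] * fs) + 1L):floor(crop_s[2] * fs)
    if (max(idx) > ncol(out)) stop("crop window exceeds the epoch", call. = FALSE)
    out <- out[, idx, drop = FALSE]
  }
  out
}
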