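#' Intra-subject (individual) template: average of training trials
#'
#' Element-wise mean over a subject's training trials of one class. Averaging
#' reinforces the phase-locked SSVEP components while attenuating background
#' EEG, so template SNR grows roughly linearly in the trial count.
#'
#' @param trials non-empty list of epochs (channels x samples, common shape).
#' @return the mean matrix, with attribute `n_trials`.
#' @export
intra_template <- function(trials) {
  if (!is.list(trials) || length(trials) == 0L) {
    stop("`trials` must be a non-empty list of epochs", call. = FALSE)
  }
  dims <- dim(as.matrix(trials[[1]]))
  for (tr in trials) {
    if (!identical(dim(as.matrix(tr)), dims)) stop("trials must share a common shape", call. = FALSE)
  }
  out <- Reduce(`+`, lapply(trials, as.matrix)) / length(trials)
  attr(out, "n_trials") <- length(trials)
  out
}

#' Confidence of a labeled trial under sine-cosine references
#'
#' The ratio of the synchronization index at the trial's labeled frequency to
#' the mean index across all `K` frequencies. Values above 1 mean the labeled
#' class stands out; scale-invariant in the score vector.
#'
#' @param trial channels x samples epoch.
#' @param label class index of the trial's true stimulus.
#' @param bank a [reference_bank()] covering all classes at the trial's
#'   sample count.
#' @return the scalar confidence `C > 0`.
#' @export
trial_confidence <- function(trial, label, bank) {
  scores <- classify_msi(trial, bank)$scores
  .confidence_from_scores(scores, label)
}

.confidence_from_scores <- function(scores, label) {
  m <- mean(scores)
  if (!is.finite(m) || m <= 0) stop("degenerate score vector: non-positive mean", call. = FALSE)
  scores[label] / m
}

#' Confidence cut-off as a function of window length
#'
#' The screening threshold is `1 + ln(d)` with `d` the window length in
#' seconds (`n_samples / fs`); for 4-second trials this gives
#' `1 + ln 4 = 2.386`. An alternative `"product"` reading
#' (`1 + ln(n_samples * fs)`) is provided for sensitivity analysis; it is far
#' more conservative (see the methods vignette) and not the default.
#'
#' @param n_samples samples in the screening window.
#' @param fs sampling rate in Hz.
#' @param interpretation `"seconds"` (default) or `"product"`.
#' @return the scalar cut-off.
#' @export
confidence_cutoff <- function(n_samples, fs, interpretation = c("seconds", "product")) {
  interpretation <- match.arg(interpretation)
  .assert_scalar_num(n_samples, "n_samples")
  .assert_scalar_num(fs, "fs")
  switch(interpretation,
         seconds = 1 + log(n_samples / fs),
         product = 1 + log(n_samples * fs))
}

#' Select a donor's high-confidence trials for one class
#'
#' Keeps the trials whose confidence strictly exceeds the cut-off; iteration
#' order is trial index, and the result is a set (no duplicates). An empty
#' selection is allowed.
#'
#' @param trials list of the donor's labeled epochs for the class.
#' @param label the class index.
#' @param bank sine-cosine [reference_bank()] at the trials' sample count.
#' @param cutoff confidence cut-off; defaults to [confidence_cutoff()] at the
#'   trials' full length.
#' @return integer vector of selected trial indices, with attribute
#'   `confidence` carrying all per-trial confidences.
#' @export
select_high_confidence <- function(trials, label, bank,
                                   cutoff = NULL) {
  stopifnot(is.list(trials), length(trials) >= 1L)
  fs <- attr(bank, "fs")
  if (is.null(cutoff)) {
    if (is.null(fs)) stop("`cutoff` required when the bank has no fs attribute", call. = FALSE)
    cutoff <- confidence_cutoff(ncol(as.matrix(trials[[1]])), fs)
  }
  conf <- vapply(trials, trial_confidence, numeric(1), label = label, bank = bank)
  keep <- which(conf > cutoff)
  attr(keep, "confidence") <- conf
  keep
}

#' Inter-subject transfer template from donor selections
#'
#' Two-stage average exactly as the transfer rule prescribes: each donor's
#' selected trials are averaged first, then donor means are averaged with
#' equal weight regardless of how many trials each donor contributed. Donors
#' with an empty selection are skipped and do not enter the denominator (a
#' zero matrix would bias the template toward silence).
#'
#' @param donor_trials list over donors; each element a (possibly empty) list
#'   of that donor's selected epochs for the class.
#' @return the template matrix with attributes `n_donors` (contributing
#'   donors) and `skipped` (indices of empty donors), or `NULL` if every
#'   donor's selection is empty (caller must fall back to intra-only scoring).
#' @export
inter_template <- function(donor_trials) {
  stopifnot(is.list(donor_trials))
  nonempty <- which(vapply(donor_trials, length, integer(1)) > 0L)
  if (length(nonempty) == 0L) return(NULL)
  means <- lapply(donor_trials[nonempty], intra_template)
  out <- Reduce(`+`, means) / length(means)
  attr(out, "n_trials") <- NULL
  attr(out, "n_donors") <- length(nonempty)
  attr(out, "skipped") <- setdiff(seq_along(donor_trials), nonempty)
  out
}

#' Rank and select donor subjects by their own MSI accuracy
#'
#' Donors are ranked in descending order of the accuracy the plain
#' sine-cosine MSI classifier attains on their own full-length trials; the
#' top `n_donors` are selected, ties broken toward the lower subject index.
#'
#' @param accuracies named or unnamed numeric vector of per-candidate MSI
#'   accuracies (the test subject must not be among the candidates).
#' @param n_donors how many donors to keep; 0 gives the empty set
#'   (intra-only operation), values above the candidate count are capped with
#'   a warning.
#' @return integer vector of selected candidate indices (into `accuracies`),
#'   in descending accuracy order.
#' @export
select_donors <- function(accuracies, n_donors) {
  stopifnot(is.numeric(accuracies))
  n_donors <- as.integer(n_donors)
  if (n_donors < 0L) stop("`n_donors` must be >= 0", call. = FALSE)
  if (n_donors > length(accuracies)) {
    warning("`n_donors` exceeds the candidate pool; capping", call. = FALSE)
    n_donors <- length(accuracies)
  }
  if (n_donors == 0L) return(integer(0))
  order(accuracies, seq_along(accuracies), decreasing = c(TRUE, FALSE),
        method = "radix")[seq_len(n_donors)]
}

#' Per-subject MSI accuracy on its own data (donor ranking statistic)
#'
#' Classifies every trial of one subject with sine-cosine references at full
#' length and returns the fraction correct.
#'
#' @param dataset an `ssvep_dataset`.
#' @param subject subject index.
#' @param bank optional precomputed [reference_bank()] at full epoch length.
#' @param n_harmonics harmonics for the bank when it must be built (default 3).
#' @return accuracy in `[0, 1]`.
#' @export
msi_self_accuracy <- function(dataset, subject, bank = NULL, n_harmonics = 3L) {
  ep <- dataset$epochs[[subject]]
  M <- ncol(ep[[1]][[1]])
  if (is.null(bank)) bank <- reference_bank(dataset$stim, dataset$fs, M, n_harmonics)
  correct <- 0L; total <- 0L
  for (i in seq_along(ep)) {
    for (tr in ep[[i]]) {
      correct <- correct + (classify_msi(tr, bank)$class == i)
      total <- total + 1L
    }
  }
  correct / total
}

#' Build the intra + inter template bank for one test subject
#'
#' Convenience wrapper tying the transfer pipeline together: donors are
#' ranked by [msi_self_accuracy()] (test subject excluded), each donor's
#' trials are confidence-screened at full length against sine-cosine
#' references, and per-class inter templates are formed by [inter_template()].
#' Intra templates average the test subject's training trials.
#'
#' @param dataset an `ssvep_dataset`.
#' @param subject test subject index.
#' @param train_idx list over classes of the subject's training-trial indices
#'   (or a single integer vector applied to every class).
#' @param n_donors size of the donor set `|P|`; 0 disables transfer
#'   (intra-only scoring).
#' @param n_harmonics harmonics of the screening references (default 3).
#' @param interpretation confidence cut-off reading, see [confidence_cutoff()].
#' @return an object of class `template_bank`: `list(intra, inter, provenance)`
#'   where `intra` and `inter` are per-class template lists (`inter[[i]]` may
#'   be `NULL`) and `provenance` records donors, selected trials and
#'   confidences.
#' @export
build_template_bank <- function(dataset, subject, train_idx, n_donors = 4L,
                                n_harmonics = 3L,
                                interpretation = c("seconds", "product")) {
  interpretation <- match.arg(interpretation)
  validate_dataset(dataset)
  K <- dataset$stim$K
  if (!is.list(train_idx)) train_idx <- rep(list(train_idx), K)
  M <- ncol(dataset$epochs[[subject]][[1]][[1]])
  bank <- reference_bank(dataset$stim, dataset$fs, M, n_harmonics)
  cutoff <- confidence_cutoff(M, dataset$fs, interpretation)

  intra <- lapply(seq_len(K), function(i) {
    intra_template(dataset$epochs[[subject]][[i]][train_idx[[i]]])
  })

  inter <- vector("list", K)
  prov <- list(donors = integer(0), cutoff = cutoff, selections = NULL)
  if (n_donors > 0L) {
    pool <- setdiff(seq_along(dataset$epochs), subject)
    acc <- vapply(pool, msi_self_accuracy, numeric(1),
                  dataset = dataset, bank = bank)
    donors <- pool[select_donors(acc, n_donors)]
    selections <- vector("list", K)
    for (i in seq_len(K)) {
      donor_trials <- lapply(donors, function(p) {
        keep <- select_high_confidence(dataset$epochs[[p]][[i]], i, bank, cutoff)
        dataset$epochs[[p]][[i]][keep]
      })
      sel_idx <- lapply(donors, function(p) {
        select_high_confidence(dataset$epochs[[p]][[i]], i, bank, cutoff)
      })
      inter[[i]] <- inter_template(donor_trials)
      selections[[i]] <- sel_idx
    }
    prov <- list(donors = donors, donor_accuracy = acc, cutoff = cutoff,
                 selections = selections)
  }
  structure(list(intra = intra, inter = inter, provenance = prov),
            class = "template_bank")
}

#' Classify an epoch with the combined intra/inter template score
#'
#' The transfer-template decoder: per class, `S_i` is the synchronization
#' index against the subject's own template and `S*_i` against the
#' inter-subject transfer template; the decision statistic is the
#' sum of squares `gamma_i = S_i^2 + S*_i^2`, argmax wins (ties to the lowest
#' index). Classes without an inter template fall back to `gamma_i = S_i^2`,
#' which with an empty donor set reduces exactly to individual-template MSI.
#'
#' @param epoch channels x samples matrix.
#' @param bank a [build_template_bank()] result, or any list with `intra` and
#'   `inter` per-class template lists. Templates longer than the epoch are
#'   truncated to its prefix.
#' @return `list(class, scores)` where `scores` holds the per-class `gamma`.
#' @export
classify_iist <- function(epoch, bank) {
  epoch <- as.matrix(epoch)
  px <- .score_prep(epoch)
  m <- ncol(epoch)
  K <- length(bank$intra)
  gamma <- numeric(K)
  for (i in seq_len(K)) {
    yi <- bank$intra[[i]][, seq_len(m), drop = FALSE]
    s <- .msi_from_prep(px, .score_prep(yi))
    g <- s^2
    if (!is.null(bank$inter[[i]])) {
      ys <- bank$inter[[i]][, seq_len(m), drop = FALSE]
      g <- g + .msi_from_prep(px, .score_prep(ys))^2
    }
    gamma[i] <- g
  }
  list(class = which.max(gamma), scores = gamma)
}
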