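# Largest canonical correlation from two preps (whitened cross-covariance
# spectral norm); shares .score_prep with the MSI scorer.
.cca_rho_from_prep <- function(px, py) {
  M <- ncol(px$Z)
  Km <- px$W %*% (tcrossprod(px$Z, py$Z) / M) %*% py$W
  d2 <- eigen(tcrossprod(Km), symmetric = TRUE, only.values = TRUE)$values[1]
  min(1, sqrt(max(d2, 0)))
}

#' Maximum canonical correlation between two multichannel signals
#'
#' Finds projections `w` and `v` maximizing the correlation between `w'X` and
#' `v'Y`. Solved as the largest singular value of the whitened cross-covariance
#' `Cxx^{-1/2} Cxy Cyy^{-1/2}`; rank-deficient auto-covariances are handled by
#' the same null-space truncation as the synchronization index.
#'
#' @param x matrix, channels x samples.
#' @param y matrix with the same sample count.
#' @return an object of class `canonical_result`: `list(rho, w, v)` with
#'   `rho` in `[0, 1]` and the two weight vectors.
#' @examples
#' x <- matrix(rnorm(200), 2)
#' cca_max_correlation(x, x)$rho  # 1: a signal is perfectly correlated with itself
#' @export
cca_max_correlation <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (ncol(x) != ncol(y)) stop("`x` and `y` must have the same sample count", call. = FALSE)
  px <- .score_prep(x); py <- .score_prep(y)
  M <- ncol(px$Z)
  Km <- px$W %*% (tcrossprod(px$Z, py$Z) / M) %*% py$W
  sv <- svd(Km, nu = 1, nv = 1)
  structure(list(rho = min(1, max(0, sv$d[1])),
                 w = drop(px$W %*% sv$u),
                 v = drop(py$W %*% sv$v)),
            class = "canonical_result")
}

#' Classify an epoch by maximum canonical correlation
#'
#' The standard CCA SSVEP decoder: the epoch is scored against each class
#' reference by its largest canonical correlation and the argmax wins (ties
#' to the lowest class index).
#'
#' @inheritParams classify_msi
#' @return `list(class, scores)` with per-class `rho` values.
#' @export
classify_cca <- function(epoch, bank) {
  px <- .score_prep(as.matrix(epoch))
  scores <- vapply(bank, function(y) {
    if (ncol(y) != ncol(epoch)) stop("bank sample count mismatch", call. = FALSE)
    .cca_rho_from_prep(px, .score_prep(y))
  }, numeric(1))
  list(class = unname(which.max(scores)), scores = unname(scores))
}

#' Multi-set CCA joint spatial filtering of training trials
#'
#' Learns one spatial filter per training trial of a class so that the sum of
#' pairwise correlations between filtered trials is maximized, subject to the
#' average filtered auto-correlation being 1. The stacked filters solve the
#' generalized eigenproblem `(R - S) w = rho S w`, where `R` holds all
#' cross-trial product blocks `X_h1 X_h2'` and `S` its block diagonal. The
#' optimized class reference stacks the filtered trials row-wise.
#'
#' @param trials list of `n >= 2` training epochs (channels x samples, common
#'   shape). With a single trial the trial itself is returned as the reference
#'   (with a warning).
#' @param ridge_frac ridge added to `S` before inversion, as a fraction of
#'   `trace(S)/dim` (default 1e-8); short windows make the block diagonal
#'   ill-conditioned.
#' @return an object of class `mset_filters`: `list(filters, reference,
#'   objective)` where `filters` is an `n_channels x n` matrix (one column per
#'   trial), `reference` the `n x n_samples` optimized reference `Z_n`, and
#'   `objective` the attained objective value.
#' @export
fit_mset_cca <- function(trials, ridge_frac = 1e-8) {
  stopifnot(is.list(trials), length(trials) >= 1L)
  trials <- lapply(trials, function(tr) .norm_rows(as.matrix(tr)))
  n <- length(trials)
  nc <- nrow(trials[[1]])
  nt <- ncol(trials[[1]])
  for (tr in trials) {
    if (nrow(tr) != nc || ncol(tr) != nt) stop("trials must share a common shape", call. = FALSE)
  }
  if (n == 1L) {
    warning("single training trial: using it directly as the reference", call. = FALSE)
    return(structure(list(filters = NULL, reference = trials[[1]], objective = NA_real_),
                     class = "mset_filters"))
  }
  Xall <- do.call(rbind, trials)             # (n*nc) x nt
  Rfull <- tcrossprod(Xall)                  # raw products, no 1/M
  Smat <- matrix(0, n * nc, n * nc)
  for (h in seq_len(n)) {
    idx <- (h - 1L) * nc + seq_len(nc)
    Smat[idx, idx] <- Rfull[idx, idx]
  }
  ridge <- ridge_frac * sum(diag(Smat)) / nrow(Smat)
  Sreg <- Smat + diag(ridge, nrow(Smat))
  Wi <- .inv_sqrt(Sreg)
  A <- Wi %*% (Rfull - Smat) %*% Wi
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  w <- drop(Wi %*% e$vectors[, 1])
  # enforce the constraint (1/n) sum_h w_h' X_h X_h' w_h = 1 exactly
  w <- w * sqrt(n / drop(crossprod(w, Smat %*% w)))
  filt <- matrix(w, nrow = nc, ncol = n)
  Zn <- t(vapply(seq_len(n), function(h) drop(crossprod(filt[, h], trials[[h]])),
                 numeric(nt)))
  obj <- drop(crossprod(w, (Rfull - Smat) %*% w))
  structure(list(filters = filt, reference = Zn, objective = obj),
            class = "mset_filters")
}

#' Classify an epoch against multi-set CCA optimized references
#'
#' @param epoch channels x samples matrix.
#' @param fits list of `K` [fit_mset_cca()] results (one per class), fitted on
#'   training folds only.
#' @return `list(class, scores)` with per-class canonical correlations against
#'   each optimized reference (truncated to the epoch length).
#' @export
classify_mset <- function(epoch, fits) {
  refs <- lapply(fits, function(f) {
    if (!inherits(f, "mset_filters")) stop("`fits` must be fit_mset_cca() results", call. = FALSE)
    f$reference[, seq_len(ncol(epoch)), drop = FALSE]
  })
  classify_cca(epoch, refs)
}

#' Classify an epoch against individual (trial-averaged) templates by CCA
#'
#' Individual-template CCA: the per-class reference is the subject's own
#' average of training trials; scoring and argmax follow [classify_cca()].
#'
#' @param epoch channels x samples matrix.
#' @param templates list of `K` template matrices (see [intra_template()]),
#'   built from training folds only.
#' @return `list(class, scores)`.
#' @export
classify_itcca <- function(epoch, templates) {
  refs <- lapply(templates, function(y) y[, seq_len(ncol(epoch)), drop = FALSE])
  classify_cca(epoch, refs)
}
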