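# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Row-wise zero-mean / unit-variance scaling (sample variance, n - 1).
# Errors identify the offending channel because a flat channel usually means
# a disconnected electrode, and silent NaN propagation would poison every
# downstream eigendecomposition.
.norm_rows <- function(x, what = "channel") {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least 2 samples to normalize", call. = FALSE)
  mu <- rowMeans(x)
  x <- x - mu
  s <- sqrt(rowSums(x^2) / (ncol(x) - 1L))
  bad <- which(s == 0 | !is.finite(s))
  if (length(bad)) {
    stop(sprintf("degenerate %s %s: zero variance, cannot normalize",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  x / s
}

.assert_scalar_num <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || (positive && x <= 0)) {
    stop(sprintf("`%s` must be a single finite %snumber", name,
                 if (positive) "positive " else ""), call. = FALSE)
  }
  invisible(x)
}
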