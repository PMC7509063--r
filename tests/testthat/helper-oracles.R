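# Independent oracles, coded as literal transcriptions of the defining
# formulas and kept separate from the production implementations.

# Synchronization index via pracma::sqrtm (Denman-Beavers iteration), i.e. a
# different route to the inverse square roots than the production eigen floor.
oracle_msi <- function(x, y) {
  norm1 <- function(m) {
    m <- m - rowMeans(m)
    m / sqrt(rowSums(m^2) / (ncol(m) - 1))
  }
  x <- norm1(x); y <- norm1(y)
  M <- ncol(x)
  C11 <- x %*% t(x) / M
  C22 <- y %*% t(y) / M
  C12 <- x %*% t(y) / M
  C <- rbind(cbind(C11, C12), cbind(t(C12), C22))
  U11 <- pracma::sqrtm(C11)$Binv
  U22 <- pracma::sqrtm(C22)$Binv
  n1 <- nrow(x); n2 <- nrow(y)
  U <- rbind(cbind(U11, matrix(0, n1, n2)),
             cbind(matrix(0, n2, n1), U22))
  R <- U %*% C %*% t(U)
  lam <- eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  lp <- lam / sum(lam)
  P <- n1 + n2
  1 + sum(ifelse(lp > 0, lp * log(lp), 0)) / log(P)
}

# Largest canonical correlation via stats::cancor (QR-based, base R).
oracle_cca <- function(x, y) {
  stats::cancor(t(x), t(y))$cor[1]
}

# A noise-free single-class trial: harmonic series mixed to channels.
make_clean_trial <- function(freq, fs = 128, n_samples = 512, n_channels = 8,
                             amplitudes = 1 / (1:3), phase = 0) {
  tt <- seq_len(n_samples) / fs
  src <- rep(0, n_samples)
  for (h in seq_along(amplitudes)) {
    src <- src + amplitudes[h] * sin(2 * pi * h * freq * tt + phase)
  }
  gains <- seq(1, 0.6, length.out = n_channels)
  outer(gains, src)
}

# Small cached datasets shared by several test files.
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dataset(
        synthetic_spec(n_subjects = 3, n_trials = 6, fs = 128,
                       subject_snr_db = c(-8, -6, -4), seed = 42))
    }
    cache
  }
})
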