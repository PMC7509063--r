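#' Stimulus configuration for an SSVEP speller
#'
#' Describes the set of flicker frequencies (and optional stimulation phases)
#' of the target matrix. Frequencies must be strictly positive and pairwise
#' distinct; phases default to zero for every class.
#'
#' @param frequencies numeric vector of stimulus frequencies in Hz (one per class).
#' @param phases optional numeric vector of stimulation phases in radians,
#'   recycled checks apply: must have the same length as `frequencies`.
#' @param refresh_note free-text note about the display (e.g. monitor refresh),
#'   stored verbatim.
#' @return an object of class `stimulus_config` with fields `frequencies`,
#'   `phases`, `K` (number of classes) and `refresh_note`.
#' @examples
#' stimulus_config(c(10, 12, 15))
#' @export
stimulus_config <- function(frequencies, phases = NULL, refresh_note = "") {
  frequencies <- as.numeric(frequencies)
  K <- length(frequencies)
  if (K < 2L) stop("need at least 2 stimulus classes", call. = FALSE)
  if (any(!is.finite(frequencies)) || any(frequencies <= 0)) {
    stop("stimulus frequencies must be finite and strictly positive", call. = FALSE)
  }
  if (anyDuplicated(frequencies)) {
    stop("stimulus frequencies must be pairwise distinct", call. = FALSE)
  }
  if (is.null(phases)) phases <- rep(0, K)
  phases <- as.numeric(phases)
  if (length(phases) != K) stop("`phases` must have one entry per frequency", call. = FALSE)
  structure(list(frequencies = frequencies, phases = phases, K = K,
                 refresh_note = refresh_note),
            class = "stimulus_config")
}

#' The 12-class joint frequency-phase stimulus layout
#'
#' Convenience constructor for the widely used 12-target virtual keypad:
#' frequencies 9.25 to 14.75 Hz in 0.5 Hz steps, phases cycling through
#' 0, 0.5pi, pi, 1.5pi.
#'
#' @return a [stimulus_config()] with `K = 12`.
#' @export
stimulus_config_12class <- function() {
  stimulus_config(seq(9.25, 14.75, by = 0.5),
                  rep(c(0, 0.5, 1, 1.5) * pi, length.out = 12L),
                  refresh_note = "60 Hz LCD, 4 x 3 keypad")
}

#' @export
print.stimulus_config <- function(x, ...) {
  cat(sprintf("<stimulus_config> %d classes, %.2f-%.2f Hz\n",
              x$K, min(x$frequencies), max(x$frequencies)))
  invisible(x)
}

#' Sine-cosine reference signals at a stimulus frequency
#'
#' Builds the canonical SSVEP reference matrix: stacked sine/cosine pairs at
#' harmonics `1..n_harmonics` of the stimulus frequency, sampled on the grid
#' `t = 1/fs, 2/fs, ..., n_samples/fs`. Note the time axis starts at `1/fs`
#' (not 0), which fixes the phase convention of every row.
#'
#' @param freq stimulus frequency in Hz (positive scalar).
#' @param fs sampling rate in Hz.
#' @param n_samples number of samples (columns), at least 2 for downstream
#'   use; `n_samples = 1` is allowed for point evaluation.
#' @param n_harmonics number of harmonics (default 3).
#' @return a `2 * n_harmonics` x `n_samples` matrix; row `2h - 1` is
#'   `sin(2 pi h f t)` and row `2h` is `cos(2 pi h f t)`.
#' @examples
#' y <- make_reference(10, fs = 256, n_samples = 512, n_harmonics = 3)
#' dim(y)  # 6 x 512
#' @export
make_reference <- function(freq, fs, n_samples, n_harmonics = 3L) {
  .assert_scalar_num(freq, "freq")
  .assert_scalar_num(fs, "fs")
  .assert_scalar_num(n_samples, "n_samples")
  .assert_scalar_num(n_harmonics, "n_harmonics")
  n_samples <- as.integer(n_samples)
  n_harmonics <- as.integer(n_harmonics)
  if (n_harmonics * freq >= fs / 2) {
    warning(sprintf("harmonic %d of %.3g Hz is at or above Nyquist (%g Hz)",
                    n_harmonics, freq, fs / 2))
  }
  tt <- seq_len(n_samples) / fs
  out <- matrix(0, nrow = 2L * n_harmonics, ncol = n_samples)
  for (h in seq_len(n_harmonics)) {
    out[2L * h - 1L, ] <- sin(2 * pi * h * freq * tt)
    out[2L * h, ] <- cos(2 * pi * h * freq * tt)
  }
  rownames(out) <- as.vector(rbind(paste0("sin_h", seq_len(n_harmonics)),
                                   paste0("cos_h", seq_len(n_harmonics))))
  attr(out, "freq") <- freq
  attr(out, "fs") <- fs
  out
}

#' Reference bank covering every stimulus class
#'
#' @param stim a [stimulus_config()].
#' @param fs sampling rate in Hz.
#' @param n_samples samples per reference.
#' @param n_harmonics harmonics per reference (default 3).
#' @return a list of `K` reference matrices (see [make_reference()]).
#' @export
reference_bank <- function(stim, fs, n_samples, n_harmonics = 3L) {
  stopifnot(inherits(stim, "stimulus_config"))
  out <- lapply(stim$frequencies, make_reference, fs = fs,
                n_samples = n_samples, n_harmonics = n_harmonics)
  names(out) <- sprintf("f%.2f", stim$frequencies)
  attr(out, "fs") <- fs
  attr(out, "n_harmonics") <- n_harmonics
  out
}

#' Specification of a synthetic multi-subject SSVEP cohort
#'
#' Parameters of the generator used throughout the test-bench: each trial is a
#' harmonic series at the class frequency (amplitudes decaying as 1/h by
#' default), with a subject-specific phase offset standing in for individual
#' visual latency, projected to the electrode montage through a fixed forward
#' vector and buried in white or 1/f ("pink") noise at a subject-specific SNR.
#' A fraction of trials (`lapse_rate`) contains noise only, emulating
#' attention lapses.
#'
#' @param n_subjects number of subjects (default 10).
#' @param n_trials trials per class per subject (default 15).
#' @param n_channels electrodes (default 8, an occipital montage).
#' @param duration_s trial length in seconds (default 4).
#' @param fs sampling rate in Hz (default 256; configurable everywhere).
#' @param harmonic_amplitudes per-harmonic source amplitudes (default `1/h`
#'   for three harmonics).
#' @param subject_snr_db per-subject signal-to-noise ratio in dB (recycled to
#'   `n_subjects`). The default spreads subjects from -16 to -7 dB, giving a
#'   cohort of weak through strong responders whose template-based decoding
#'   accuracy spans roughly 60-100% at full windows (broadband SNR; the
#'   in-band SNR after the implicit matched filtering of the decoders is
#'   considerably higher, as in band-passed EEG).
#' @param subject_phase_jitter_rad standard deviation of the per-subject phase
#'   offset (radians) applied on top of the nominal stimulation phase.
#' @param noise_model `"pink"` (default) or `"white"`.
#' @param channel_mixing forward matrix (`n_channels` rows) mapping the source
#'   to electrodes; default is a smooth occipital gain gradient, one source.
#' @param lapse_rate probability in `[0, 1]` that a trial is pure noise.
#' @param seed integer seed; generation is fully reproducible from it.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = 10L, n_trials = 15L, n_channels = 8L,
                           duration_s = 4, fs = 256,
                           harmonic_amplitudes = 1 / seq_len(3L),
                           subject_snr_db = seq(-16, -7, length.out = n_subjects),
                           subject_phase_jitter_rad = 0.2,
                           noise_model = c("pink", "white"),
                           channel_mixing = NULL,
                           lapse_rate = 0, seed = 1L) {
  noise_model <- match.arg(noise_model)
  for (nm in c("n_subjects", "n_trials", "n_channels", "duration_s", "fs")) {
    .assert_scalar_num(get(nm), nm)
  }
  if (lapse_rate < 0 || lapse_rate > 1) stop("`lapse_rate` must be in [0, 1]", call. = FALSE)
  if (any(harmonic_amplitudes < 0) || all(harmonic_amplitudes == 0)) {
    stop("`harmonic_amplitudes` must be non-negative with at least one positive entry",
         call. = FALSE)
  }
  subject_snr_db <- rep_len(as.numeric(subject_snr_db), n_subjects)
  if (is.null(channel_mixing)) {
    channel_mixing <- matrix(seq(1, 0.6, length.out = n_channels), ncol = 1L)
  }
  channel_mixing <- as.matrix(channel_mixing)
  if (nrow(channel_mixing) != n_channels) {
    stop("`channel_mixing` must have `n_channels` rows", call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects), n_trials = as.integer(n_trials),
                 n_channels = as.integer(n_channels), duration_s = duration_s, fs = fs,
                 harmonic_amplitudes = harmonic_amplitudes,
                 subject_snr_db = subject_snr_db,
                 subject_phase_jitter_rad = subject_phase_jitter_rad,
                 noise_model = noise_model, channel_mixing = channel_mixing,
                 lapse_rate = lapse_rate, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# 1/f-amplitude noise via spectral shaping of white noise; returns nc x n.
.pink_noise <- function(nc, n) {
  out <- matrix(0, nc, n)
  f <- c(1, seq_len(n - 1L))            # avoid dividing DC by zero
  shape <- 1 / sqrt(pmin(f, n - f + 1L))  # symmetric 1/sqrt(f) amplitude profile
  for (ch in seq_len(nc)) {
    spec <- stats::fft(stats::rnorm(n)) * shape
    out[ch, ] <- Re(stats::fft(spec, inverse = TRUE)) / n
  }
  out
}

#' Simulate a multi-subject SSVEP dataset
#'
#' Generates `n_subjects x K x n_trials` epochs with the layout
#' subject -> class -> trial, each a `n_channels x (duration_s * fs)` matrix.
#' The source of class `i` is `sum_h a_h sin(2 pi h f_i t + phi_i + phi_p)`
#' with `phi_p` the subject's latency-induced phase offset; noise is scaled so
#' the realized per-trial SNR equals the subject's requested SNR exactly.
#' Lapse trials carry noise only (at the power a signal trial would have had)
#' and are flagged.
#'
#' @param spec a [synthetic_spec()].
#' @param stim a [stimulus_config()]; defaults to the 12-class layout.
#' @return an object of class `ssvep_dataset`: list with `epochs`
#'   (`epochs[[subject]][[class]][[trial]]`), `lapse` (per subject, a
#'   `K x n_trials` logical matrix), `fs`, `stim`, `spec`, and
#'   `subject_phase_offsets`.
#' @examples
#' ds <- simulate_dataset(synthetic_spec(n_subjects = 2, n_trials = 3,
#'                                       duration_s = 1, fs = 128, seed = 7))
#' dim(ds$epochs[[1]][[1]][[1]])  # 8 x 128
#' @export
simulate_dataset <- function(spec, stim = stimulus_config_12class()) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(stim, "stimulus_config"))
  M <- as.integer(round(spec$duration_s * spec$fs))
  tt <- seq_len(M) / spec$fs
  H <- length(spec$harmonic_amplitudes)
  nc <- spec$n_channels
  with_seed(spec$seed, {
    phase_off <- stats::rnorm(spec$n_subjects, 0, spec$subject_phase_jitter_rad)
    epochs <- vector("list", spec$n_subjects)
    lapse <- vector("list", spec$n_subjects)
    for (p in seq_len(spec$n_subjects)) {
      snr_lin <- 10^(spec$subject_snr_db[p] / 10)
      cls <- vector("list", stim$K)
      lp <- matrix(FALSE, stim$K, spec$n_trials)
      for (i in seq_len(stim$K)) {
        f <- stim$frequencies[i]
        src <- rep(0, M)
        for (h in seq_len(H)) {
          src <- src + spec$harmonic_amplitudes[h] *
            sin(2 * pi * h * f * tt + stim$phases[i] + phase_off[p])
        }
        # one harmonic source driving every column of the forward matrix
        sig <- spec$channel_mixing %*% matrix(src, nrow = ncol(spec$channel_mixing),
                                              ncol = M, byrow = TRUE)
        p_sig <- mean(sig^2)
        trials <- vector("list", spec$n_trials)
        for (h in seq_len(spec$n_trials)) {
          is_lapse <- stats::runif(1) < spec$lapse_rate
          noise <- if (spec$noise_model == "pink") .pink_noise(nc, M) else
            matrix(stats::rnorm(nc * M), nc, M)
          p_noise_target <- p_sig / snr_lin
          noise <- noise * sqrt(p_noise_target / mean(noise^2))
          trials[[h]] <- if (is_lapse) noise else sig + noise
          lp[i, h] <- is_lapse
        }
        cls[[i]] <- trials
      }
      epochs[[p]] <- cls
      lapse[[p]] <- lp
    }
    structure(list(epochs = epochs, lapse = lapse, fs = spec$fs, stim = stim,
                   spec = spec, subject_phase_offsets = phase_off),
              class = "ssvep_dataset")
  })
}

#' @export
print.ssvep_dataset <- function(x, ...) {
  M <- ncol(x$epochs[[1]][[1]][[1]])
  cat(sprintf("<ssvep_dataset> %d subjects x %d classes x %d trials, %d ch x %d samples @ %g Hz\n",
              length(x$epochs), x$stim$K, length(x$epochs[[1]][[1]]),
              nrow(x$epochs[[1]][[1]][[1]]), M, x$fs))
  invisible(x)
}

#' Validate the structural invariants of a dataset
#'
#' Checks the nested subject/class/trial layout, common epoch geometry and
#' metadata coherence. Called by the loader; exported because the benchmark
#' refuses malformed input with the same diagnostics.
#'
#' @param ds an `ssvep_dataset`.
#' @return `ds`, invisibly; errors name the offending field.
#' @export
validate_dataset <- function(ds) {
  if (!inherits(ds, "ssvep_dataset")) stop("not an ssvep_dataset", call. = FALSE)
  for (fld in c("epochs", "fs", "stim")) {
    if (is.null(ds[[fld]])) stop(sprintf("dataset field `%s` missing", fld), call. = FALSE)
  }
  K <- ds$stim$K
  dims <- dim(ds$epochs[[1]][[1]][[1]])
  for (p in seq_along(ds$epochs)) {
    if (length(ds$epochs[[p]]) != K) {
      stop(sprintf("subject %d: expected %d classes, found %d", p, K,
                   length(ds$epochs[[p]])), call. = FALSE)
    }
    for (i in seq_len(K)) {
      for (tr in ds$epochs[[p]][[i]]) {
        if (!identical(dim(tr), dims)) {
          stop(sprintf("subject %d class %d: epoch shape mismatch", p, i), call. = FALSE)
        }
        if (any(!is.finite(tr))) {
          stop(sprintf("subject %d class %d: non-finite samples", p, i), call. = FALSE)
        }
      }
    }
  }
  invisible(ds)
}
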