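---
title: "Template-based synchronization decoding of SSVEPs: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-based synchronization decoding of SSVEPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssvepmsi)
```

## The decoding problem

A steady-state visually evoked potential (SSVEP) speller presents `K`
flickering targets, each tagged with a frequency `f_i` (here, the common
12-target layout: 9.25 to 14.75 Hz in 0.5 Hz steps, with stimulation phases
cycling through 0, 0.5&pi;, &pi;, 1.5&pi;). Gazing at a target entrains
occipital EEG at `f_i` and its harmonics; the decoder's job is to recover the
gazed target from a multichannel epoch `X` (channels &times; samples), as
fast as possible.

This package implements a family of decoders around the **multivariate
synchronization index (MSI)** and benchmarks them under a common
cross-validation harness:

* `classify_msi()` — MSI against sine-cosine reference matrices
  (`make_reference()`): stacked `sin(2 pi h f t)` / `cos(2 pi h f t)` rows
  at harmonics `h = 1..N_h`, with the time axis starting at `t = 1/Fs`.
* `classify_cca()`, `classify_mset()`, `classify_itcca()` — the standard
  contrast methods (canonical correlation against references, multi-set CCA
  joint spatial filtering of training trials, individual-template CCA).
* `classify_iist()` — MSI against *templates*: the subject's own
  trial-averaged template `Y_i` and a confidence-screened inter-subject
  transfer template `Y*_i`, combined per class as the sum of squares
  `gamma_i = S_i^2 + (S*_i)^2`.
* `decode_trial()` / `run_benchmark()` — the dynamic-window adaptive
  threshold: per-window probability ratios multiplied into a joint
  probability that stops the trial once it crosses a duration-dependent
  cut-off.

## The synchronization index

For an epoch `X` (`N1 x M`) and reference `Y` (`N2 x M`), both normalized
channel-wise to zero mean and unit variance, the joint covariance `C` (with
`1/M` scaling) is block-whitened by the inverse square roots of its two
auto-covariance blocks, and `S` is one minus the normalized eigenvalue
entropy of the transformed correlation matrix `R`:

`S = 1 + sum_i lambda'_i log(lambda'_i) / log(P)`, with
`lambda'_i = lambda_i / tr(R)` and `P = N1 + N2`.

`S = 1` for perfectly synchronized signals, `S = 0` when `R` is the
identity (no cross-correlation). Useful closed forms, used as test anchors:
with `X = Y` and `N` channels, `S = 1 - log N / log 2N`, so the two-channel
self-synchrony is exactly 0.5.

Numerical choices:

* Covariance uses the `1/M` scaling as the index is conventionally defined
  (not `1/(M-1)`); the distinction cancels under exact whitening.
* Inverse square roots are computed by symmetric eigendecomposition;
  directions with eigenvalue below `1e-10 * trace/dim` are truncated (zero
  weight in the whitener) with a warning. Short windows with 8 or more
  channels can be numerically rank-deficient, and near-noise-free epochs are
  nearly rank-1; *flooring* small eigenvalues instead of truncating them
  would amplify rounding noise in the null space by `~1/sqrt(floor)` and let
  junk directions dominate the transformed correlation matrix, which in
  piloting flipped adjacent-class decisions on clean data at 0.5 s windows.
* `R` is symmetrized as `(R + R')/2` before its eigendecomposition, and the
  entropy uses natural logarithms (the base cancels).
* Normalization is per channel, not global; the index is invariant to
  channel order and per-channel sign flips, which the tests assert.
* Score ties in every classifier break toward the lowest class index —
  deterministic and testable.

## Transfer templates and confidence screening

The intra-subject template `Y_i` is the element-wise mean of the subject's
training trials of class `i` (`intra_template()`); averaging `N` phase-locked
trials grows template SNR roughly `N`-fold in power.

The inter-subject template `Y*_i` (`inter_template()`) transfers data from
donor subjects. Since donors vary in quality, two screens apply:

1. **Donor ranking** (`select_donors()`): candidate donors are ranked by the
   accuracy plain sine-reference MSI attains on their own full-length data;
   the top `|P|` donors are used (default `|P| = 4`).
2. **Trial confidence** (`trial_confidence()`): a donor trial enters the
   template only if its MSI score at its labeled frequency, divided by its
   mean score over all `K` frequencies, exceeds a cut-off. The cut-off is
   `1 + ln(d)` with `d` the screening window in seconds — `1 + ln 4 = 2.39`
   for 4-second trials. A `"product"` reading (`1 + ln(N_t * F_s)`) is also
   implemented behind a switch; at typical geometries it evaluates to ~12.8,
   a level no realistic trial reaches, so the window-seconds reading is the
   default. Screening always uses full-length trials and sine-cosine
   references with `N_h = 3`.

The template is a two-stage average — each donor's selected trials first,
then donor means with equal weight — so prolific donors do not dominate.
Donors contributing nothing to a class are dropped from that class's
denominator rather than entering as zero matrices, which would bias the
template toward silence. If every donor is empty for a class, the class
falls back to intra-only scoring (`gamma_i = S_i^2`); with `|P| = 0` the
decoder reduces exactly to individual-template MSI.

## The adaptive threshold

Fixed-window decoding wastes time on easy trials and rushes hard ones. The
dynamic-window rule scores cumulative prefixes (initial window 0.5 s,
increment 0.5 s — `window_schedule()`), converts each window's `gamma` into
probability ratios `r_{m,i} = gamma_{m,i} / mean_k(gamma_{m,k})` (unit mean
by construction), and multiplies them into a joint probability
`J_i <- J_i * r_{m,i}`. The trial stops at the first window where
`max_i J_i` reaches the cut-off `T_c(d)` for the current duration `d`; the
argmax wins. A trial that exhausts its data below the cut-off is *invalid*
and yields no decision — deliberately so, as such trials (attention lapses,
weak responses) would otherwise convert to errors.

Design choices worth knowing:

* The "new data segment" at each step is the cumulative prefix, not the
  0.5 s increment alone; templates are built once at full length and sliced
  to the prefix, keeping a single provenance for `Y_i`.
* The cut-off is duration-dependent, one value per bucket
  (&le;1 s, 1–2 s, 2–3 s, 3–4 s), with candidate grids of 1–2 by 0.05,
  1–4 by 0.1, 3–8 by 0.2, and 3–16 by 0.4 respectively; a constant-cut-off
  mode exists (`threshold_schedule(value)`).
* `grid_search_threshold()` tunes the schedule on training folds only.
  Candidates whose invalid-trial proportion exceeds 20% *strictly* are
  discarded; survivors are ranked by training accuracy, then shorter mean
  decision time, then smaller cut-offs. Because decision traces do not
  depend on the cut-off, traces are computed once and every candidate is
  replayed vectorized, which keeps the search effectively free.
* The search itself is coordinate ascent over buckets, earlier durations
  first, iterated to stability from both the most conservative and the most
  permissive corner of the grid. A single greedy sweep from the conservative
  corner proved brittle: when late buckets sit above what weak subjects'
  joint probabilities can reach, the feasibility ceiling forces the first
  bucket into over-aggressive values. A `"full"` product-grid mode exists
  for small grids.
* **Leave-one-out training traces.** When a training trial is scored during
  the grid search, its own class template is rebuilt without it
  (`(n Y_i - x)/(n - 1)`). Scoring a trial against a template it was
  averaged into saturates training accuracy at any stopping time, and the
  decision-time tie-break then drives the schedule toward the earliest
  windows; the leave-one-out estimate is unbiased for unseen trials and
  restores the intended accuracy/speed trade-off.

## Evaluation

`cv_plan()` partitions each class's 15 trials into three folds of five.
Accuracy (`cv_accuracy()`) is the *unweighted mean of fold-wise percentages*
of correctly classified valid trials — not the pooled ratio; the two differ
when invalid-trial filtering unbalances folds, and the fold-mean definition
is the one used throughout.

`itr()` implements Wolpaw's information transfer rate
`B = log N + P log P + (1-P) log((1-P)/(N-1))`, `ITR = 60 B / T`. The
default convention is base-2 (bits/min). A natural-logarithm convention is
provided as well (`convention = "nat"`) because a portion of the SSVEP
literature tabulates ITRs in that unit: with `N = 12` and `T = 5` s it maps
100% accuracy to 29.82 rather than 43.02, and the package's regression
fixture of published per-subject values reproduces under it to the printed
two decimals. The two conventions differ exactly by `ln 2`, which a test
asserts. `T` is the analysis window plus a 1 s gaze shift; for the adaptive
decoder `T` uses the mean decision time of valid trials — a convention the
literature leaves unstated, so it is a package choice, kept out of any
regression fixture.

`preprocess_epoch()` supplies the standard conditioning for raw recordings:
zero-phase (forward-backward) order-4 Butterworth band-pass, 6–80 Hz, then
cropping to the 4 s stimulation segment starting 0.15 s after onset. Order
and phase handling are configurable; only the band and the IIR family are
canonical.

## The synthetic cohort

`simulate_dataset()` generates the study geometry without recordings: 10
subjects &times; 12 classes &times; 15 trials, 8 channels, 4 s at a
configurable sampling rate (256 Hz default; the benchmark and acceptance
runs use 128 Hz, which keeps all three harmonics below Nyquist and halves
the compute). Each trial is a harmonic series (amplitudes `1/h`, three
harmonics) at the class frequency with the class's stimulation phase plus a
subject-specific phase offset (SD 0.2 rad) standing in for individual visual
latency, projected to electrodes through a smooth occipital gain gradient,
in white or `1/f`-shaped ("pink", the default) noise scaled so the realized
broadband per-trial SNR equals the subject's requested SNR exactly.

The default cohort spreads subject SNRs from −16 to −7 dB. That range was
chosen so the cohort spans weak through strong responders: template-based
decoding then runs from roughly 60% to 100% at full windows with the
qualitative window-length curves real cohorts show, while short windows
remain hard. Note the SNR is *broadband*; the decoders' implicit matched
filtering sees a much higher in-band SNR, as band-passed EEG would. A
`lapse_rate` parameter injects pure-noise trials (flagged) to emulate
attention lapses; confidence screening is expected to reject these at a
higher rate than clean trials, which a test verifies.

What the generator deliberately does **not** emulate: non-sinusoidal
subject-specific response waveforms, correlated background EEG shared
across classes and channels, electrode artifacts, or session drift. Two
consequences matter for interpreting results. First, sine-cosine references
are the *true* signal model here, so reference-based methods (CCA, MSI) are
relatively stronger than on real EEG, where individual templates capture
waveform structure references cannot; passing benchmarks therefore
demonstrate correctness and qualitative orderings among template methods,
not the real-data superiority of templates over references. Second,
synthetic score contrasts are somewhat sharper than real ones, so the
adaptive decoder's joint probabilities grow faster and its absolute decision
times should not be read as real-data predictions.

## Problem sizes and determinism

All randomness flows from explicit integer seeds (`synthetic_spec(seed=)`,
`cv_plan(seed=)`, `run_benchmark(seed=)`); generation is bitwise
reproducible and the benchmark is deterministic given its seed. The shipped
test suite and the acceptance script use a 10-subject, 128 Hz cohort
(21,600 epoch-window scorings per fixed-window method), which runs the full
seven-method comparison in a few minutes on one core. Larger cohorts,
higher rates, or the 256 Hz default simply scale linearly.

## Known limitations

* The confidence cut-off's window-seconds reading is a considered
  interpretation of an ambiguous convention; both readings are implemented
  and logged, and conclusions should be checked under both when stakes are
  high.
* The grid search optimizes buckets coordinate-wise; with strongly coupled
  buckets the full product mode is the reference, at combinatorial cost.
* Invalid trials are excluded from accuracy (valid-trial accuracy), matching
  the definition used for the cross-validated percentages; systems that must
  act on every trial should also inspect `invalid_prop`.
* MAT/HDF5 ingestion of public datasets is out of scope here; datasets
  serialize via RDS with full validation, and any epoch collection shaped
  subject &rarr; class &rarr; trial can be assembled directly in R.
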