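---
title: "Cleaning mobile EEG recorded during full-body movement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cleaning mobile EEG recorded during full-body movement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegcleanse)
```

EEG recorded while the participant moves freely — exergaming, ambulatory
monitoring, neuroergonomics — is contaminated by motion, muscle, ocular and
line-noise artifacts that dwarf the neural signal. `eegcleanse` implements a
fully automated, hardware-independent cleaning pipeline for such recordings:
no reference sensors, no manual component inspection, every decision logged.
This vignette explains the model behind each stage, the tunable parameters
and their defaults, what the synthetic-session generator does and does not
emulate, and the numerical choices that shape edge-case behavior.

## The pipeline at a glance

A session moves through a fixed sequence:

1. **Ingestion and segmentation** — parse the raw OpenBCI-style text export,
   synchronize to the gameplay interval, cut per-mini-game segments.
2. **Channel screening** — remove high-impedance, flatline, low-correlation
   and amplitude-outlier channels.
3. **Artifact Subspace Reconstruction (ASR)** — calibrate a statistical model
   of clean EEG on the session itself and reconstruct transient
   high-variance bursts; reject windows that stay pervasively noisy.
4. **Zero-phase high-pass FIR filtering** — duration-adaptive cutoff,
   applied *after* ASR.
5. **Dual extended-infomax ICA** — one decomposition of the ASR-cleaned
   data, one of the filtered data, and three ICA-to-signal mappings.
6. **Component classification and hybrid voting** — per-component category
   probabilities (pluggable classifier), four OR-combined retention
   criteria, and reconstruction of the brain-only signal.

Each stage can mark a session *excluded* (too few clean channels, nothing
left after window rejection, ICA infeasible, no brain components); exclusion
is a status carried in the result, never an error, so batch processing
continues.

## Channel screening

Screening is deliberately two-step. High-impedance channels — mean absolute
amplitude strictly above 48,000 µV, the signature of a detached or bridged
electrode — are removed first. Only then are the remaining criteria
evaluated on the survivors, so a single 90,000 µV channel cannot inflate the
robust statistics that the other detectors depend on.

The three second-step criteria are:

* **Flatline**: a contiguous run of at least 5 s with variance within
  `flatline_var_tol` (default `1e-10` µV², tolerating float jitter on
  digitally constant segments).
* **Low correlation**: Pearson correlation below 0.85 with the per-sample
  median of the *other* channels. The leave-one-out median is the robust
  reference; a channel cannot vote for itself.
* **Noisy**: per-channel standard deviation converted to a robust z-score
  (median and scaled MAD across channels), flagged above `|z| > 4`. If the
  MAD is zero — all amplitudes identical — the criterion is skipped with a
  warning rather than dividing by zero.

The mean-amplitude statistic is the mean *absolute* amplitude by default
(`impedance_stat = "mean_abs"`): a signed mean would let large symmetric
artifacts cancel to zero. The signed variant is available for comparison
with toolchains that use it.

Sessions with fewer than `min_channels = 4` survivors are excluded — ICA
downstream needs several channels to produce meaningful components.

## ASR: model, calibration, correction

ASR assumes that clean EEG occupies a low-dimensional subspace with stable
second-order statistics, and that movement artifacts are transient
excursions of much larger variance along identifiable directions.

**Clean reference.** The recording is divided into 1-s windows
(`calib_window_s`); each channel's RMS per window is robust-z-scored across
windows, and a window joins the calibration reference only if every
channel's z lies within `ref_z_bounds = c(-3.5, 5)` — asymmetric because
high-amplitude excursions are the artifact signature while unusually quiet
windows are rarely harmful. The fraction of the session accepted as clean is
reported per session; it is a useful data-quality indicator in its own
right.

**Calibration.** On the masked data the pipeline computes the principal
components of the covariance, a symmetric square-root mixing estimate `M`,
and a per-component RMS bound `mean + burst_criterion × sd` over calibration
windows. Two numerical choices matter here:

* The windows used for the threshold statistics have the *detection* window
  length (0.5 s), not the 1-s reference-mask length. RMS variance scales
  inversely with window length, so calibrating bounds on longer windows than
  detection uses would systematically inflate false positives on perfectly
  clean data.
* Components whose calibration eigenvalue is numerically zero (below
  `1e-9` of the largest) get an infinite threshold. They span the null space
  of a rank-deficient background; their "RMS" is float noise, and comparing
  it with equally tiny bounds flags windows at random.

**Correction.** Detection slides 0.5-s windows with 50% overlap. In a
window, components exceeding their bound are re-estimated from the retained
subspace through `M` (the standard ASR reconstruction operator); windows
with no exceedance pass through bit-identically, which gives the identity
limit as `burst_criterion → ∞`. Overlapping corrected windows are blended
with raised-cosine weights. If *every* signal-subspace component exceeds its
bound there is no clean direction to reconstruct from; the window is zeroed
and left for window rejection to remove. Channel means are removed before
calibration and restored on output — ASR needs zero-mean input, but the
filtering stage that would remove drift runs later by design.

**Ordering.** ASR runs on channel-screened, *unfiltered* data. A sharp
high-pass applied first would smear brief high-amplitude artifacts across
neighbouring samples; running ASR first lets it see artifacts at their
original temporal extent. The high-pass then removes the remaining drift
before ICA.

**Window rejection.** After correction, non-overlapping windows in which
more than `window_criterion = 0.05` of the components still exceed their
bounds are dropped from the time axis. The accounting is done in the
calibration component basis, which has exactly one component per channel.

The four criterion values (0.85, 4, 3, 0.05) follow the EEGLAB parameter
names and are all exposed on `asr_config()`. The channel and line-noise
criteria act as logged pre-checks on the calibration data; after channel
screening they are normally silent.

## High-pass filtering

The kernel is a Hamming-windowed sinc low-pass, normalized to exactly unit
DC gain, subtracted from a unit impulse (spectral inversion). This makes the
coefficient sum exactly zero — DC is nulled to machine precision — while the
passband stays within a fraction of a percent of unity. At order 208 and
125 Hz the transition band is roughly 2 Hz wide, which is why direct
window-method design struggles at a 0.5 Hz cutoff and spectral inversion is
used instead.

The kernel is symmetric (linear phase) and applied by centred convolution
with reflection padding, so the output has zero phase at every frequency and
the input's length. Sessions shorter than `duration_threshold_s = 120` s use
a 0.5 Hz cutoff — few slow cycles fit into a short recording, and a higher
cutoff would eat into them disproportionately — while longer sessions use
1.0 Hz; a duration exactly at the boundary takes the long-session cutoff.
The threshold itself is a package default, configurable and recorded in the
recording's history.

## Dual ICA and cross-application

Extended infomax (natural-gradient infomax with kurtosis-driven switching
between super- and sub-Gaussian score functions) is fitted separately to the
ASR-cleaned and the filtered version of each session, with consecutive seeds
so the two fits draw distinct permutation streams. Implementation follows
the `runica` conventions: block updates with learning-rate annealing when
successive weight changes turn more than 60°, blow-up restarts at a gentler
rate, convergence at a weight-change below `1e-6`, a 512-iteration cap. The
sphering matrix is `inv(sqrtm(cov))`, so sphered data have identity
covariance. Components are ordered by the explained variance of their mixing
columns and sign-fixed (largest topography loading positive), making indices
stable across runs; with the seed recorded in the model, refits are
bit-identical.

Rank matters: ASR reconstruction and channel removal reduce dimensionality,
so the decomposition detects rank and restricts itself to the principal
subspace, with the projection folded into the sphere matrix (the stored
`unmixing = weights %*% sphere` is `r × k`). Recordings with fewer than
`20·k²` samples are excluded — below that, an unmixing matrix of `k²` free
parameters is badly underdetermined.

Three mappings feed the voting stage: clean model on clean data, filtered
model on filtered data, filtered model on clean data. Activations are always
`unmixing %*% data` of the *target* version and the mixing matrix is
recomputed as the pseudo-inverse on transfer, so reconstruction identities
hold exactly. If the filtered fit fails, voting proceeds on the single
clean-to-clean mapping; if both fail, the session is excluded.

## Classification and the hybrid vote

Per-component probabilities over the seven standard categories (Brain,
Muscle, Eye, Heart, Line Noise, Channel Noise, Other) come from a pluggable
classifier. Externally computed tables — e.g. an ICLabel run in another
toolchain — can be loaded from CSV; the built-in heuristic classifier makes
the pipeline self-contained. It scores transparent features — alpha- and
beta-band excess over a flat spectrum and a negative 1/f log-log slope for
Brain, high-frequency broadband dominance for Muscle, heavy-tailed
low-frequency transients for Eye, mains-frequency concentration for Line
Noise, single-channel topography concentration for Channel Noise — and
softmaxes them, so featureless components come out diffuse rather than
confidently labelled. It is a stand-in with no claim of equivalence to a
trained classifier: it is conservative on broadband components and
recognises no cardiac signature (Heart keeps a small constant score).

An IC is retained as brain if **any** of four criteria fires:

* **C1** — Brain probability ≥ 0.6 in at least two versions.
* **C2** — Brain probability ≥ 0.7 in one version and no version
  contradicts it. A contradiction is a non-Brain argmax with probability
  ≥ 0.6, a definition chosen symmetric with C1's confidence level.
* **C3** — weighted mean Brain probability strictly above 0.5 (equal
  weights by default).
* **C4** — a strict majority of versions has Brain as argmax with
  probability ≥ 0.5.

All fired criteria are recorded per IC, not just the first. With a single
version, C1 cannot fire and C4 reduces to that version's own verdict. The
0.5 thresholds on C3/C4 and the contradiction rule are package defaults for
quantities the four-criterion scheme leaves open; they are configuration
parameters, not claims about any other implementation.

The brain-only signal is reconstructed from the filtered version by default
(it feeds downstream analysis); the target is switchable. Retaining every
IC reproduces the input to machine precision; retaining none marks the
session excluded — both are tested identities, not incidental behavior.

## Validation metrics

The metric suite mirrors what one needs to compare cleaning methods without
task labels: spectral entropy (base-2 Shannon entropy of the normalized
Welch PSD, DC excluded, averaged over channels), relative alpha (8–13 Hz)
and beta (13–30 Hz) band power, the alpha-to-total SNR proxy, mean
per-channel Pearson correlation to the raw signal, effective rank (singular
values above `1e-7` of the largest), retained-IC summaries, and paired
t-tests with Cohen's d (paired variant: mean difference over the standard
deviation of differences). Channel-wise z-scoring and L2 normalization are
provided for cross-method comparisons; all the spectral metrics and rank are
invariant under positive per-channel rescaling, which the tests verify
numerically.

The Welch estimator uses demeaned 2-s segments with 50% overlap and a
*rectangular* taper by default. This is a deliberate choice: the entropy
metric is a spectral-concentration measure, and a Hamming taper's mainlobe
spreads even a perfectly pure on-bin tone over three bins, flooring its
entropy near 1.1 bits; with rectangular segments an on-bin tone concentrates
in a single bin and the entropy approaches zero, while a white spectrum
still approaches `log2(n_bins)`. The cost is higher sidelobe leakage for
off-bin narrowband signals, which none of the relative band metrics here is
sensitive to at 0.5 Hz resolution; a Hamming taper remains available on the
estimator. Because entropy depends on the binning, absolute entropy values
are comparable only within one PSD configuration.

Degenerate inputs are handled explicitly: zero-variance difference vectors
in the paired test return a `degenerate` flag (with `t = d = 0, p = 1` when
the methods agree exactly) instead of propagating NaN, and zero retained
ICs yield `NA` summaries with `defined = FALSE`.

## The synthetic-session generator

No public recording accompanies this pipeline's validation data, so the
generator is a first-class module: it produces 16-channel, 125 Hz sessions
(60 s by default) with known ground truth — clean data, mixing matrix,
per-kind artifact masks, and the exact artifact contribution — plus session
metadata with a gameplay interval and two mini-games so ingestion is
exercised end to end. Everything is deterministic given the seed, and the
clean sources depend on the seed alone, so the `gt_profile()` (still
baseline: mild line noise only) and `mvmt_profile()` (10% motion-burst
coverage, blinks, one uncorrelated channel, line noise) presets built from
one seed share identical clean data for paired comparisons.

Design choices worth knowing when interpreting test results:

* The background is six sources — two amplitude-modulated 10 Hz alpha
  oscillations, one 20 Hz beta oscillation, three 1/f noise processes — at
  about 20 µV RMS, mixed through a volume-conduction-like matrix: a shared
  loading pattern plus a ±25% perturbation, singular values floored at a
  tenth of the largest. Scalp channels are therefore strongly mutually
  correlated, as real referenced EEG is; that is the regime the
  median-reference screening criterion presupposes.
* Envelope modulation is ±15% and the 1/f processes carry a white spectral
  floor (and are flat below 1 Hz, the band the high-pass owns). This keeps
  the background's 0.5-s windowed RMS stationary, so planted 20× bursts are
  *unambiguously* outside the calibration distribution — the fixtures test
  burst detection, not the detector's behavior on borderline
  nonstationarity.
* Motion bursts are spatially coherent: each burst projects up to three
  noise sources through a topography dominated by a common mode, like
  electrodes moving together. Spatially independent per-channel noise would
  destroy inter-channel correlation and make screening remove every channel
  of a movement session.
* Planted channel artifacts are unambiguous by construction: the impedance
  offset is twice the 48,000 µV threshold, the noisy channel is an 8×
  amplitude-scaled copy (an outlier that stays correlated with its
  neighbours), the flatline lasts 6 s against the 5 s rule.
* Sensor noise defaults to zero, keeping the clean background's rank equal
  to the source count; a `sensor_noise_rms` parameter adds a full-rank
  white floor when noisy dry-electrode hardware is the point of a study.

What the generator does **not** emulate: biophysical head geometry and
realistic topographies, cardiac artifacts, electrode drift and slow
impedance changes, the heavy-tailed nonstationarity of real background EEG,
or ICLabel's decision surface. Passing tests therefore demonstrate that each
stage implements its contract and recovers planted, well-separated
artifacts — not that real-data retention rates will match any particular
study.

## Problem sizes and reproducibility

The test suite and the acceptance script run on desk-scale problems chosen
to exercise every code path: 60-s 16-channel sessions for the pipeline
stages, a 4-channel/4-source 60-s fixture for blind-source recovery, 5k vs
50k samples for the consistency property, and a small cohort of four paired
GT/MVMT sessions in the acceptance script. Every random draw flows from an
explicit seed; rerunning any stage or the whole pipeline with the same seed
is bit-identical, which the tests assert with `identical()` rather than a
tolerance.

```{r, eval = FALSE}
ss <- generate_session(mvmt_profile(synth_spec(seed = 5)))
res <- run_pipeline(ss$recording, seed = 42)
glance(res)
autoplot(res$report$votes)
```

## Known limitations

* The ASR variant uses a fixed calibration basis (non-Riemannian, offline);
  there is no streaming mode.
* The heuristic classifier is a transparent stand-in, not a trained model;
  real studies should supply external probability tables.
* The cutoff-duration boundary (120 s), the C3/C4 voting thresholds, the
  clean-reference z bounds and the per-mini-game time adjustments are
  package defaults for quantities their sources leave open; all are
  configuration, logged in reports and recording histories.
* Line noise is handled by ASR's pre-check and the Line Noise IC category,
  not by a notch filter.
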