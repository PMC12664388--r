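# eegcleanse

Automated cleaning of mobile EEG recorded during full-body movement.

EEG captured while participants move freely — exergaming, ambulatory
monitoring, neuroergonomics — is dominated by motion, muscle, ocular and
line-noise artifacts. `eegcleanse` is an end-to-end, hardware-independent
preprocessing pipeline for such recordings: it needs no reference sensors or
manual component inspection, and it logs every decision it makes. It is
aimed at researchers running 16-channel consumer-grade (OpenBCI-style)
setups in movement-rich paradigms, but every stage is parameterized for
other montages and sampling rates.

## The method

A session passes through a fixed sequence of stages, any of which can mark
it excluded instead of erroring:

1. **Ingest & segment** — parse the raw `%`-header text export, synchronize
   to the gameplay interval `[t_start − b, t_end + b)` (buffer `b = 2` s),
   and cut per-mini-game segments labelled
   `{condition}/{participant}/{minigame}_{index}`.
2. **Channel screening** — remove channels with mean |amplitude| > 48,000 µV
   (poor contact) first, then evaluate on the survivors: flatline runs ≥ 5 s,
   correlation < 0.85 with the leave-one-out cross-channel median, and
   robust amplitude outliers |z| > 4 with z = (σᵢ − med σ)/(1.4826·MAD σ).
3. **ASR** — select a clean calibration reference (per-window, per-channel
   robust-z bounds), compute principal components of the calibration
   covariance with per-component RMS bounds μⱼ + 3·σⱼ (burst criterion 3),
   and in each sliding 0.5-s window reconstruct exceeding components from
   the retained subspace via the calibration mixing estimate
   R = M·(TₖM)⁺·Tₖ. Windows where > 5% of components still exceed are
   dropped (window criterion 0.05). ASR runs on *unfiltered* data.
4. **Zero-phase FIR high-pass** — Hamming-sinc kernel by spectral inversion,
   order 208, cutoff 0.5 Hz for sessions < 120 s and 1.0 Hz otherwise;
   centred convolution with reflection padding (exactly linear phase).
5. **Dual extended-infomax ICA** — separate decompositions of the
   ASR-cleaned and filtered versions, and three ICA-to-signal mappings
   (clean→clean, filtered→filtered, filtered→clean).
6. **Hybrid voting** — per-IC probabilities over the seven standard
   categories (pluggable classifier; a transparent spectral/topographic
   heuristic is built in), then retain an IC if any of: (C1) Brain p ≥ 0.6
   in ≥ 2 versions; (C2) Brain p ≥ 0.7 in one version and no non-Brain
   argmax ≥ 0.6 anywhere; (C3) mean Brain p > 0.5; (C4) strict majority of
   versions with Brain argmax at p ≥ 0.5. The brain-only signal is
   `A[, retained] · s[retained, ]`.

A validation-metric suite (spectral entropy, relative band powers,
alpha-power SNR proxy, correlation to raw, effective rank, retained-IC
summaries, paired t/Cohen's d) and a seeded synthetic-session generator with
planted artifacts and exact ground truth complete the package.

## Worked example

```r
library(eegcleanse)

# a seeded 60-s movement session: 10% motion-burst coverage, blinks,
# one uncorrelated channel, line noise — with ground truth attached
ss  <- generate_session(mvmt_profile(synth_spec(seed = 5)))
res <- run_pipeline(ss$recording, seed = 42)
res
#> <eegcleanse_result> status: ok
#> <cleaning_report>
#>   channels: 15/16 retained
#>   asr: clean reference 88.3%, reconstructed 24.8%, 0 window(s) dropped
#>   filter: 0.5 Hz cutoff (60 s session)
#>   ics: 6/9 retained as brain
```

Reading this: screening removed the planted uncorrelated channel (15/16);
88.3% of the session qualified as ASR's clean calibration reference; 24.8%
of samples fell in reconstructed windows (the planted bursts plus blink
excursions); the 60-s session got the 0.5 Hz cutoff; and 6 of the 9
independent components (the session's effective rank) were retained as
brain-related by the voting rule. `glance(res)` returns these as a one-row
tibble, `tidy(res)` the per-IC vote trace with Brain probabilities and fired
criteria, and `res$recording` the brain-only signal.

A command-line interface wraps the same functions
(`exec/eegcleanse <synth|ingest|screen|asr|filter|ica|label|metrics|run-all>`),
moving recordings between stages as CSV with JSON reports.

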