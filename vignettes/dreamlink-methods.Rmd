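---
title: "Methods: simulating and scoring two-way dream communication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and scoring two-way dream communication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dreamlink)
```

## The problem

Interactive-dreaming experiments deliver questions to a sleeping
participant — tones, light flashes, spoken words, or taps — during REM
sleep, and read answers back out of the polysomnogram. A lucid dreamer who
knows they are dreaming can answer volitionally, either with full-range
left-right eye movements (which produce conjugate deflections on the two
EOG channels that stand out sharply from ordinary REM-sleep eye movements)
or with selective facial-muscle contractions (zygomatic for yes/up,
corrugator for no/down), since facial twitches escape REM atonia.

The raw data behind such studies are not publicly deposited, so this
package rebuilds the entire pipeline on *synthetic* data with exact ground
truth: answer codecs, per-team stimulus schedulers, a polysomnography
simulator, automated signal detection, multi-rater consensus
classification under REM gating, and the aggregate outcome and
chance-level statistics. The published aggregate tables ship as plain-text
fixtures, so the headline numbers are recomputed from inputs, never
hard-coded in the analysis path.

## Answer codes and timing

Two eye-movement codes are implemented. **Gaze Morse** maps a leftward
movement to a dot and a rightward movement to a dash; the alphabet is
restricted to the digits 0–9 plus P (plus) and M (minus). Stimulus trains
use 300-ms dots, 900-ms dashes, a 300-ms pause after every symbol and a
3000-ms pause between characters, with a 20-s answer window
(`timing_params()`). The answer "9" — four rightward dashes then one
leftward dot — therefore spans
$4 \times 900 + 300 + 4 \times 300 = 5100$ ms, about 5 s:

```{r}
pulse_train_duration_ms(pulse_train(encode_morse("9")))
```

**LR count** signals the integer $n$ by $n$ left-right pairs (LR = 1,
LRLR = 2, ...). Decoding is deliberately strict: a sequence that is not a
strict L-first alternation ending on R returns `"malformed"`, and a gaze
pattern decoding to a Morse letter outside the task alphabet returns
`"unrecognized"`. The protocols define only the task alphabet, so an
out-of-alphabet decode is evidence of a detection failure; surfacing it
(rather than guessing) lets the consensus layer treat it as no usable
response. Facial codes use two contractions of one muscle per answer, and
an identity mapping from tap count to contraction count in the tactile
counting task (the original procedure does not state the mapping; identity
is the only assumption that preserves the answer space).

## Stimulus schedulers

Three session designs are generated (`schedule_tlr_cues()`,
`schedule_french_session()`, `run_german_night()`). Where the protocols
say "about" — cues "at about 30-s intervals", words "every 10 s with a
jitter" — the jitter law is not stated; we use uniform jitter (±2 s on the
30-s cue interval, ±1 s on the 10-s word interval) because it is the
simplest bounded choice, and expose the parameters. The nocturnal
Morse-problem protocol is a state machine evaluated on a 0.1-s tick (the
original is event-driven with no stated resolution): problems start after
5 min of stable REM or immediately on a lucidity signal, intensity is an
abstract ordinal level that increments with each problem (no calibrated
dB/lux values are reported), stimulation stops on arousal or on leaving
REM, and the participant is awoken 2 min after the last eye signal.
Whether stimulation should stop permanently after a correct answer is not
specified; we stop the current problem and continue with the next.
Dutch-design math problems use solutions 1–4, mirroring the US design the
Dutch group adapted (their solution range is not stated).

## The synthetic polysomnogram

`render_record()` builds an eight-channel record (three EEG, two EOG, chin
EMG, corrugator and zygomatic EMG) at 500 Hz. No generative model of the
signals is published, so the simulator is deliberately minimal and its
parameters are exposed in `sim_params()`:

* **EOG background**: white noise (SD 10 µV per channel) plus
  Poisson-arriving conjugate saccades (half-sine, 120 ms, 25 µV,
  0.3 s⁻¹) during REM epochs.
* **Volitional signals**: 0.5-s ramp-hold-return deflections, opposite
  polarity on the two EOG channels (left movement: left channel positive),
  with amplitude `signal_to_background_ratio` (default 3) times the
  background saccade amplitude. The ratio is the sensitivity knob: the
  operative property is amplitude contrast, not waveform shape.
* **EMG**: chin noise SD 2 µV in REM (atonia) versus 10 µV in wake;
  facial contractions as 0.3-s high-frequency bursts at 8× the 2-µV
  facial baseline.
* **EEG**: noise with an alpha component in wake and a theta component in
  REM — enough to look stage-dependent, with no claim of microstructure
  realism.

`simulate_hypnogram()` produces a true stage sequence (normal design:
first REM period 68 min after sleep onset; narcolepsy design: REM within
about a minute of a 20-min nap) and derives up to three scorer tracks by
flipping each epoch to a random other stage with a confusion probability.
`simulate_raters()` models the four signal raters: truth with probability
`p_correct`, otherwise a ±1 miscount or a miss, with a configurable
confidence distribution (all-HIGH by default, since no empirical
distribution is reported).

What a green test establishes, therefore, is that the *pipeline* — codec,
scheduler, detector, consensus, statistics — is correct on a world with
the stated timing, amplitude-contrast and rater-behavior properties. It
does not establish detector performance on real polysomnography, where
artifact structure, electrode drift and rater psychology are all richer
than this generator.

## Detection choices

Human raters judged signals by eye with no common criterion, so the
automated detector is this artifact's own operationalization
(`detector_params()`). It thresholds the differential EOG at 2.5× the
MAD-based robust SD of a 60-s pre-window baseline, labels direction by
sign, enforces a 0.3-s onset-to-onset refractory period, groups events
into trains with a 2.0-s maximum gap, and decodes via the codec. One
criterion was added to that rule: a detection must stay beyond threshold
for at least 0.25 s. The reason is structural. The baseline MAD tracks the
noise floor (saccades are sparse), while background saccades reach well
above any noise-scaled threshold; no amplitude threshold can sit above the
saccades and below the volitional signals across configurations. Duration
separates them cleanly: background saccades last ~0.1 s, volitional scans
~0.5 s. This is also why accuracy collapses when the amplitude ratio drops
to 1 — at signal amplitudes comparable to background, noise fragments the
above-threshold runs below the duration criterion, so signals stop being
detected rather than being mis-decoded.

EMG bursts are counted from a 50-ms moving-RMS envelope at 4× the baseline
RMS, merging crossings closer than 0.25 s.

## Consensus rules and gating

Trials enter the summary only if the epoch was scored REM by at least 2 of
the 3 independent scorers *and* the session contained a signal-verified
lucid dream (`gate_trial()`). A lucidity signal is itself required to fall
in a consensus-REM epoch (this is not explicit in the source procedures;
`detect_svld(require_rem = FALSE)` relaxes it).

`classify_eye_trial()` evaluates the cascade in the order CORRECT (≥3 of 4
raters report the expected count) → INCORRECT (≥3 agree on one other
count) → NO_RESPONSE (≥3 report no signal) → AMBIGUOUS (≥3 saw a response
without count consensus, or 2 raters saw none) → AMBIGUOUS as the default
for anything else (e.g. a 2–2 split between two counts). Only
high-confidence ratings are used; a non-high rating becomes an abstention
— it is removed from every tally while the thresholds stay absolute, which
is the strictest reading of "only high-confidence ratings counted" against
fixed 4-rater rule statements. The experimenter's original rating carries
no confidence grade and is treated as HIGH. Facial trials use the
majority cascade over (muscle, count) pairs with the expected count fixed
at two.

## Statistics

`summarize_trials()` tabulates outcomes per task with percentages rounded
half-up to one decimal (matching the published table's formatting; the
prose value of 60.1% for no-response conflicts with the printed 96/158 =
60.8%, and the table is taken as canonical). `fleiss_kappa()` implements
the standard formula $(\bar P - \bar P_e)/(1 - \bar P_e)$; the published
agreement values (0.71 overall, 0.70 for communication periods) cannot be
recomputed because the raw 1652-epoch scorer data are unavailable, so the
tests verify the formula against brute-force pair enumeration and the
near-zero behavior under independent ratings. `fisher_exact()` computes
the exact hypergeometric tail, one-sided ("greater") by default because
the chance-level claims are directional; "response" in the lucid versus
non-lucid contrast means any of correct/incorrect/ambiguous, with a
correct-only definition available — both clear the p < 0.001 bound on the
fixture counts by orders of magnitude.

## Numerical and degenerate-input conventions

All onsets are seconds from record start; epochs are 0-based, half-open
30-s windows. An all-zero record yields a zero threshold and, by strict
inequality, zero detections. A single-category rating matrix has chance
agreement 1; kappa is defined as 1 when agreement is perfect and an error
otherwise. Empty schedules, empty REM periods and zero-trial summaries
return empty objects rather than errors. EDF export uses 1-s data records
and 16-bit quantization against per-channel physical ranges; round-trip
error is bounded by one quantization step.

## Known limitations

* The simulator's spectral content is schematic; it supports detector
  logic tests, not benchmarking against clinical data.
* The automated detector is not a model of the human raters (who
  disagreed with each other); rater variability is simulated at the
  judgment level instead, by `simulate_raters()`.
* The published kappa values and per-participant breakdowns are not
  reproducible from shipped fixtures; only aggregate table arithmetic is.
* Real-time operation, audio synthesis and lucidity induction are out of
  scope; spoken stimuli are opaque payload events with expected answers.
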