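# dreamlink

Simulated two-way communication with lucid dreamers during REM sleep.

## What this is for

Interactive-dreaming experiments pose questions to a sleeping participant
— spoken math problems, Morse-coded tone/light trains, taps, words — and
read volitional answers back out of the polysomnogram: full-range
left-right eye movements on the EOG channels, or selective facial-muscle
contractions (zygomatic = yes, corrugator = no) on facial EMG. Trials are
scored by multiple raters and count only when the epoch was REM by scorer
consensus (≥2 of 3) inside a session with a signal-verified lucid dream
(SVLD).

The raw recordings behind such studies are not deposited, so `dreamlink`
rebuilds the whole pipeline at desk scale on synthetic data with exact
ground truth, for methodologists who want to exercise, stress or extend
the analysis chain:

* **codec** — Morse stimulus trains (300-ms dots, 900-ms dashes, 300-ms
  symbol pauses, 3000-ms character pauses) and answer codes: gaze Morse
  (left = dot, right = dash) and LR counts (LR = 1, LRLR = 2, ...);
* **protocol** — per-team stimulus schedulers: ~30-s lucidity-reactivation
  cues, 10–15-s cueing, 10 blocks × 6 words with 1-min OFF periods, and a
  nocturnal Morse-problem state machine with intensity ramping;
* **psg_sim** — 8-channel polysomnography with REM saccade background,
  embedded high-amplitude answer signals, chin atonia, EMG bursts,
  hypnograms with simulated scorer confusion, and simulated raters;
* **detect** — automated eye-movement and muscle-burst detection on the
  differential EOG / EMG RMS envelope;
* **consensus** — the 4-rater classification cascade
  (CORRECT / INCORRECT / AMBIGUOUS / NO_RESPONSE) under REM + SVLD gating;
* **stats** — outcome tables, Fleiss' kappa, exact Fisher tests and the
  chance-level control analyses.

The central consensus rule: a trial is CORRECT when ≥3 of the 4 raters
(three naive raters plus the experimenter) report the expected signal
count with high confidence; ≥3 agreeing on another count is INCORRECT; ≥3
reporting no signal is NO_RESPONSE; response-without-count-consensus, or 2
no-response raters, is AMBIGUOUS. Agreement uses Fleiss' kappa
(P̄ − P̄ₑ)/(1 − P̄ₑ); chance levels use one-sided exact hypergeometric
tests.

## Worked example

One trial: a spoken "8 minus 6" at t = 70 s, answered 3 s later with two
left-right eye movements (LRLR = 2), rendered into a 500-Hz record,
detected, decoded, rated and classified.

```r
library(dreamlink)

sched <- structure(list(
  events = data.frame(onset_s = 70, modality = "SPOKEN",
                      payload = "8 minus 6", intensity = 1L,
                      expected_answer = 2L),
  session_design = "USA_TLR"), class = "stimulus_schedule")
plan <- data.frame(stimulus_index = 1L, action = "hit", answer = 2L,
                   code_kind = "LR_COUNT", latency_s = 3)
sim <- render_record(sched, plan, duration_s = 100, seed = 42)
sim$record
#> <psg_record> 8 channels x 50000 samples @ 500 Hz (100.0 s)

(ev <- detect_eye_movements(sim$record, c(70, 90)))
#>   onset_s direction peak_uv duration_s
#> 1   73.03         L   183.2      0.434
#> 2   73.73         R   183.5      0.434
#> 3   74.45         L   191.1      0.412
#> 4   75.13         R   181.3      0.438
count_answer(ev, "LR_COUNT")
#> [1] 2
```

Four detected deflections, alternating L/R at ~180 µV on the differential
EOG (background saccades stay near 50 µV), decoding to the answer 2.
Simulated raters then judge the trial and the consensus rule classifies
it:

```r
j <- simulate_raters(2L, p_correct = 0.9, seed = 7)
j$count
#> [1] NA  2  2  2
classify_eye_trial(2, j)
#> [1] "CORRECT"   # 3 of 4 raters matched the expected count
```

The packaged published tables reproduce the headline aggregates:

```r
s <- summarize_trials(load_outcome_fixture())
s[s$team == "Total", c("n_trials", "correct", "pct_correct",
                       "no_response", "pct_no_response")]
#>    n_trials correct pct_correct no_response pct_no_response
#> 10      158      29        18.4          96            60.8

chance_analyses(list(correct = 29, incorrect = 5, ambiguous = 28,
                     no_response = 96),
                load_control_fixture()$outcomes)
#> <chance_report> responses (any): lucid 0.392 vs non-lucid 0.034, Fisher p = 2.74e-25
```

158 gated trials with 29 correct answers (18.4%); responses are ~12×
more frequent during lucid than non-lucid REM attempts (62/158 vs 13/379,
p ≪ 0.001).

## Command line

```sh
Rscript inst/cli/dreamlink simulate --design french --seed 7 --out out/
Rscript inst/cli/dreamlink replicate-tables --out out/
Rscript inst/cli/dreamlink detect --edf out/rec.edf --from 70 --to 90 --out out/
Rscript inst/cli/dreamlink report --trials trials.csv \
    --controls inst/extdata/nonlucid_controls.json --out out/
```

Every run writes `run_log.json` (config hash, seed, package version), so
outputs are re-derivable from the log alone.

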