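#' @title Problem generation and stimulus scheduling
#' @name protocol
#' @description
#' Each laboratory used a different session design: TLR cueing at ~30-s
#' intervals during REM (USA) or every 10-15 s (Netherlands), a nocturnal
#' Morse-coded problem protocol with intensity ramping (Germany), and a
#' blocked spoken-word design with 1-min OFF periods (France). These
#' functions generate random arithmetic problems under each design's answer
#' constraints and lay out timed stimulus schedules.
NULL

.problem_schemes <- c("USA_1_4", "DE_FULL_0_9", "DE_SIMPLE_2_5", "NL")

#' Generate a random arithmetic problem
#'
#' Problems are simple additions/subtractions subject to the scheme's
#' constraints: `USA_1_4` and `NL` solutions lie in 1..4 (the range
#' answerable by LR-pair counts), `DE_FULL_0_9` has operands and solution in
#' 0..9 (full gaze-Morse range), `DE_SIMPLE_2_5` has solutions in 2..5 (the
#' simplified LR-count variant).
#'
#' @param scheme One of `"USA_1_4"`, `"DE_FULL_0_9"`, `"DE_SIMPLE_2_5"`,
#'   `"NL"`.
#' @param seed Optional integer; when given, generation is deterministic.
#' @return A `problem`: list with `operand_a`, `operator` (`"PLUS"`/
#'   `"MINUS"`), `operand_b`, `solution`, `scheme`, `text`.
#' @export
generate_problem <- function(scheme = .problem_schemes, seed = NULL) {
  scheme <- match.arg(scheme)
  if (!is.null(seed)) set.seed(as.integer(seed))
  sol_range <- switch(scheme,
    USA_1_4 = 1:4, NL = 1:4, DE_FULL_0_9 = 0:9, DE_SIMPLE_2_5 = 2:5)
  repeat {
    a <- sample(0:9, 1L)
    b <- sample(0:9, 1L)
    op <- sample(c("PLUS", "MINUS"), 1L)
    sol <- if (op == "PLUS") a + b else a - b
    if (sol %in% sol_range && sol >= 0L && sol <= 9L &&
        a >= 0L && a <= 9L && b >= 0L && b <= 9L) break
  }
  structure(list(operand_a = a, operator = op, operand_b = b,
                 solution = sol, scheme = scheme,
                 text = paste(a, tolower(op), b)),
            class = "problem")
}

#' @export
print.problem <- function(x, ...) {
  cat(sprintf("<problem> %s = %d [%s]\n", x$text, x$solution, x$scheme))
  invisible(x)
}

.schedule_df <- function(onset_s = numeric(0), modality = character(0),
                         payload = character(0), intensity = integer(0),
                         expected_answer = integer(0)) {
  data.frame(onset_s = as.numeric(onset_s), modality = as.character(modality),
             payload = as.character(payload), intensity = as.integer(intensity),
             expected_answer = as.integer(expected_answer),
             stringsAsFactors = FALSE)
}

.new_schedule <- function(events, design) {
  stopifnot(all(diff(events$onset_s) > 0))
  structure(list(events = events, session_design = design),
            class = "stimulus_schedule")
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat(sprintf("<stimulus_schedule> %s: %d events over %.1f s\n",
              x$session_design, nrow(x$events),
              if (nrow(x$events)) diff(range(x$events$onset_s)) else 0))
  invisible(x)
}

#' Schedule lucidity-reactivation cues within one REM period
#'
#' Cues start at REM onset and repeat until the REM period ends or the
#' per-period cap (10 cues) is reached: roughly every 30 s (2-s uniform
#' jitter) for the USA design, uniformly every 10-15 s for the Dutch one.
#' Cueing pauses during supplied arousal windows and resumes afterwards.
#'
#' @param rem_start_s,rem_end_s REM period bounds in seconds from record
#'   start. An empty interval yields an empty schedule.
#' @param design `"USA_TLR"` or `"NL_TLR"`.
#' @param seed Optional integer for deterministic jitter.
#' @param max_cues Cap on cues per REM period (default 10).
#' @param arousal_windows Optional 2-column matrix of (start, end) arousal
#'   windows; no cue is delivered inside one.
#' @return A `stimulus_schedule` of TLR cue events.
#' @export
schedule_tlr_cues <- function(rem_start_s, rem_end_s,
                              design = c("USA_TLR", "NL_TLR"),
                              seed = NULL, max_cues = 10L,
                              arousal_windows = NULL) {
  design <- match.arg(design)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (!is.finite(rem_start_s) || !is.finite(rem_end_s) ||
      rem_end_s <= rem_start_s) {
    return(.new_schedule(.schedule_df(), design))
  }
  gap <- function() {
    if (design == "USA_TLR") 30 + stats::runif(1, -2, 2)
    else stats::runif(1, 10, 15)
  }
  in_arousal <- function(t) {
    if (is.null(arousal_windows) || !nrow(arousal_windows)) return(FALSE)
    any(t >= arousal_windows[, 1] & t <= arousal_windows[, 2])
  }
  onsets <- numeric(0)
  t <- rem_start_s
  while (length(onsets) < max_cues && t < rem_end_s) {
    if (!in_arousal(t)) {
      onsets <- c(onsets, t)
      t <- t + gap()
    } else {
      t <- t + 1 # paused: poll again after the arousal
    }
  }
  n <- length(onsets)
  ev <- .schedule_df(onset_s = onsets, modality = rep("TONE", n),
                     payload = rep("TLR_CUE", n), intensity = rep(1L, n),
                     expected_answer = rep(NA_integer_, n))
  .new_schedule(ev, design)
}

# word -> expected facial answer for the semantic task
.french_words <- data.frame(
  payload = c("up", "down", "mixed"),
  expected_muscle = c("ZYGOMATIC", "CORRUGATOR", "CORR_THEN_ZYG"),
  stringsAsFactors = FALSE)

#' Schedule a blocked spoken-word (semantic task) session
#'
#' Ten blocks of six randomly chosen words (up / down / mixed), one word
#' every ~10 s with uniform jitter, blocks separated by 1-min OFF periods of
#' white noise, stimulation starting 1 min into the nap; the whole session
#' spans about 20 min.
#'
#' @param n_blocks,stimuli_per_block Block structure (defaults 10 and 6).
#' @param isi_s Nominal within-block inter-stimulus interval, seconds.
#' @param jitter_s Half-width of the uniform jitter on each gap.
#' @param off_s OFF (white noise only) period between blocks, seconds.
#' @param start_s Delay from nap start to first block, seconds.
#' @param block_s Block duration, seconds.
#' @param seed Optional integer for deterministic word choice and jitter.
#' @return A `stimulus_schedule` of WORD events; attribute `off_periods` is
#'   a 2-column matrix of OFF windows.
#' @export
schedule_french_session <- function(n_blocks = 10L, stimuli_per_block = 6L,
                                    isi_s = 10, jitter_s = 1, off_s = 60,
                                    start_s = 60, block_s = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  onsets <- numeric(0); words <- character(0); muscles <- character(0)
  offs <- matrix(numeric(0), ncol = 2)
  for (b in seq_len(n_blocks)) {
    b0 <- start_s + (b - 1L) * (block_s + off_s)
    t <- b0
    for (i in seq_len(stimuli_per_block)) {
      if (i > 1L) t <- t + isi_s + stats::runif(1, -jitter_s, jitter_s)
      w <- .french_words[sample.int(nrow(.french_words), 1L), ]
      onsets <- c(onsets, t)
      words <- c(words, w$payload)
      muscles <- c(muscles, w$expected_muscle)
    }
    if (b < n_blocks) offs <- rbind(offs, c(b0 + block_s, b0 + block_s + off_s))
  }
  n <- length(onsets)
  ev <- .schedule_df(onset_s = onsets, modality = rep("WORD", n),
                     payload = words, intensity = rep(1L, n),
                     expected_answer = rep(NA_integer_, n))
  ev$expected_muscle <- muscles
  sched <- .new_schedule(ev, "FR_BLOCKS")
  attr(sched, "off_periods") <- offs
  sched
}

#' Run the nocturnal Morse-problem state machine
#'
#' Emulates the night protocol: during each REM period, a stimulus modality
#' (tone vs light) is chosen at random; Morse-coded problems begin after
#' 5 min of stable REM, or immediately after a lucidity eye signal. Stimulus
#' intensity (an abstract ordinal level) increases with each new problem;
#' tone frequency (470/600 Hz) and LED color (red/green) alternate per
#' problem so the dreamer can spot problem boundaries. Stimulation stops on
#' arousal or on leaving REM; if 2 min pass after the last eye signal
#' without an awakening, the participant is awoken. The state machine is
#' evaluated on a 0.1-s tick.
#'
#' @param hooks List describing the simulated night:
#'   `stages` (vector of 30-s epoch stage labels, truth),
#'   `arousal_times` (numeric vector of arousal onsets, seconds),
#'   `eye_signals` (data.frame with `onset_s` and `kind` in
#'   `"lucidity"`/`"answer"`).
#' @param seed Integer seed for modality and problem randomness.
#' @param scheme Problem scheme (default `"DE_FULL_0_9"`).
#' @param timing A [timing_params()] object.
#' @param stable_rem_s Stable-REM wait before stimulating (default 300 s).
#' @param signal_timeout_s Awaken after this long with no eye signal
#'   (default 120 s).
#' @param tick_s Scheduler tick (default 0.1 s).
#' @return List with `schedule` (a `stimulus_schedule` whose events carry
#'   `problem` payloads, per-problem intensities, `tone_hz`/`led_color`
#'   markers and `expected_answer`) and `trace` (data.frame of state
#'   transitions: `t_s`, `state`, `note`).
#' @export
run_german_night <- function(hooks, seed = 1L, scheme = "DE_FULL_0_9",
                             timing = timing_params(), stable_rem_s = 300,
                             signal_timeout_s = 120, tick_s = 0.1) {
  stopifnot(is.list(hooks), !is.null(hooks$stages))
  set.seed(as.integer(seed))
  stages <- as.character(hooks$stages)
  total_s <- length(stages) * 30
  arousals <- sort(as.numeric(hooks$arousal_times %||% numeric(0)))
  eye <- hooks$eye_signals %||%
    data.frame(onset_s = numeric(0), kind = character(0))
  stage_at <- function(t) stages[[min(length(stages), floor(t / 30) + 1L)]]
  arousal_in <- function(t0, t1) any(arousals > t0 & arousals <= t1)
  signals_in <- function(t0, t1) eye[eye$onset_s > t0 & eye$onset_s <= t1, ]

  ev <- NULL
  trace <- data.frame(t_s = numeric(0), state = character(0),
                      note = character(0))
  note <- function(t, s, n) {
    trace <<- rbind(trace, data.frame(t_s = t, state = s, note = n))
  }

  state <- "WAIT_REM"; rem_since <- NA_real_
  last_signal <- NA_real_; problem_idx <- 0L; modality <- NA_character_
  t <- 0
  while (t < total_s) {
    tn <- t + tick_s
    st <- stage_at(t)
    sig <- signals_in(t - tick_s, t)
    if (nrow(sig)) last_signal <- max(sig$onset_s)

    if (state == "WAIT_REM") {
      if (st == "REM") {
        if (is.na(rem_since)) {
          rem_since <- t
          modality <- sample(c("TONE", "LIGHT"), 1L)
          note(t, "WAIT_REM", "REM onset; modality chosen")
        }
        lucid_now <- nrow(sig) && any(sig$kind == "lucidity")
        if (arousal_in(t - tick_s, t)) {
          rem_since <- NA_real_
          note(t, "WAIT_REM", "arousal; stability clock reset")
        } else if (lucid_now || (t - rem_since) >= stable_rem_s) {
          state <- "STIMULATE"
          note(t, "STIMULATE",
               if (lucid_now) "lucidity signal" else "stable REM reached")
          next
        }
      } else {
        rem_since <- NA_real_
      }
      t <- tn
    } else if (state == "STIMULATE") {
      if (st != "REM" || arousal_in(t - tick_s, t)) {
        state <- "WAIT_REM"; rem_since <- NA_real_; problem_idx <- 0L
        note(t, "WAIT_REM",
             if (st != "REM") "left REM; stimulation stopped"
             else "arousal; stimulation stopped")
        t <- tn
        next
      }
      problem_idx <- problem_idx + 1L
      prob <- generate_problem(scheme)
      train <- pulse_train(encode_morse(prob$text), timing)
      dur_s <- pulse_train_duration_ms(train) / 1000
      ev <- rbind(ev, data.frame(
        onset_s = t, modality = modality, payload = prob$text,
        intensity = problem_idx,
        expected_answer = as.integer(prob$solution),
        tone_hz = if (modality == "TONE") c(470, 600)[1 + problem_idx %% 2]
                  else NA_real_,
        led_color = if (modality == "LIGHT") c("red", "green")[1 + problem_idx %% 2]
                    else NA_character_,
        stringsAsFactors = FALSE))
      note(t, "STIMULATE", sprintf("problem %d: %s", problem_idx, prob$text))
      # present the train, then wait out the answer window (tick-quantized)
      t_end <- t + dur_s + timing$answer_window_s
      answered <- FALSE
      while (t < min(t_end, total_s)) {
        t <- t + tick_s
        if (stage_at(t) != "REM" || arousal_in(t - tick_s, t)) {
          state <- "WAIT_REM"; rem_since <- NA_real_; problem_idx <- 0L
          note(t, "WAIT_REM", "stimulation interrupted")
          break
        }
        sig <- signals_in(t - tick_s, t)
        if (nrow(sig)) {
          last_signal <- max(sig$onset_s)
          if (any(sig$kind == "answer")) answered <- TRUE
        }
        if (!is.na(last_signal) && (t - last_signal) >= signal_timeout_s) {
          note(t, "AWAKEN", "2-min eye-signal timeout")
          state <- "DONE"
          break
        }
      }
      if (state == "DONE") break
      if (answered) note(t, "STIMULATE", "answer received; next problem")
    }
    if (state == "DONE") break
  }
  sched <- .new_schedule(
    if (is.null(ev)) {
      e <- .schedule_df(); e$tone_hz <- numeric(0); e$led_color <- character(0)
      e
    } else ev, "DE_NIGHT")
  list(schedule = sched, trace = trace)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
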