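#' @title Synthetic polysomnography with ground-truth answer signals
#' @name psg_sim
#' @description
#' Generates everything the downstream pipeline consumes, with exact ground
#' truth: hypnograms (a true 30-s epoch stage sequence plus up to three
#' simulated scorers with configurable confusion), multichannel physiology
#' (two EOG channels with spontaneous rapid-eye-movement background and
#' embedded large-amplitude volitional "maximal horizontal scan" signals,
#' chin EMG with REM atonia, corrugator/zygomatic EMG with contraction
#' bursts, three EEG channels of stage-colored noise), and simulated signal
#' raters with configurable accuracy and confidence.
NULL

.stage_levels <- c("W", "N1", "N2", "N3", "REM")

#' Simulator parameters
#'
#' All amplitudes are in microvolts. The operative property is the contrast
#' between background rapid eye movements and embedded volitional signals:
#' `signal_to_background_ratio` (default 3) multiplies the background
#' saccade amplitude to give the volitional amplitude.
#'
#' @param rate Sampling rate, samples/s (default 500, the acquisition rate).
#' @param noise_uv Per-channel EOG/EEG noise SD.
#' @param saccade_uv Background saccade amplitude per EOG channel.
#' @param saccade_rate_hz Poisson rate of spontaneous saccades during REM.
#' @param saccade_dur_s Background saccade duration.
#' @param signal_to_background_ratio Volitional / background amplitude ratio.
#' @param move_dur_s Duration of one volitional eye movement
#'   (0.1-s ramp, hold, 0.1-s return).
#' @param move_gap_s Gap between successive volitional movements.
#' @param chin_rem_uv,chin_wake_uv Chin EMG noise SD during REM (atonia) and
#'   wake.
#' @param facial_noise_uv Facial EMG baseline noise SD.
#' @param burst_gain Facial contraction burst amplitude as a multiple of
#'   baseline.
#' @param burst_dur_s,burst_gap_s Facial burst duration and inter-burst gap.
#' @param calibration_uv Amplitude calibration marker value.
#' @return A `sim_params` list.
#' @export
sim_params <- function(rate = 500, noise_uv = 10, saccade_uv = 25,
                       saccade_rate_hz = 0.3, saccade_dur_s = 0.12,
                       signal_to_background_ratio = 3, move_dur_s = 0.5,
                       move_gap_s = 0.2, chin_rem_uv = 2, chin_wake_uv = 10,
                       facial_noise_uv = 2, burst_gain = 8,
                       burst_dur_s = 0.3, burst_gap_s = 0.4,
                       calibration_uv = 100) {
  structure(list(rate = rate, noise_uv = noise_uv, saccade_uv = saccade_uv,
                 saccade_rate_hz = saccade_rate_hz,
                 saccade_dur_s = saccade_dur_s,
                 signal_to_background_ratio = signal_to_background_ratio,
                 move_dur_s = move_dur_s, move_gap_s = move_gap_s,
                 chin_rem_uv = chin_rem_uv, chin_wake_uv = chin_wake_uv,
                 facial_noise_uv = facial_noise_uv, burst_gain = burst_gain,
                 burst_dur_s = burst_dur_s, burst_gap_s = burst_gap_s,
                 calibration_uv = calibration_uv),
            class = "sim_params")
}

.psg_channels <- c("EEG_F", "EEG_C", "EEG_O", "EOG_L", "EOG_R",
                   "EMG_chin", "EMG_corr", "EMG_zyg")

#' Construct a polysomnography record
#'
#' @param channels Named list of equal-length numeric vectors; names must be
#'   the standard montage (`EEG_F`, `EEG_C`, `EEG_O`, `EOG_L`, `EOG_R`,
#'   `EMG_chin`, `EMG_corr`, `EMG_zyg`), all in microvolts.
#' @param rate Sampling rate, samples/s.
#' @param calibration_uv Calibration marker amplitude (default 100).
#' @return A `psg_record`.
#' @export
psg_record <- function(channels, rate = 500, calibration_uv = 100) {
  stopifnot(is.list(channels), length(channels) > 0, rate > 0)
  if (is.null(names(channels)) || any(!nzchar(names(channels)))) {
    stop("channels must be named", call. = FALSE)
  }
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("all channels must have equal length", call. = FALSE)
  }
  structure(list(channels = channels, rate = rate,
                 n_samples = unname(lens[1]),
                 band_settings = list(EEG = c(0.3, 15), EOG = c(0.3, 15),
                                      EMG = c(10, 100)),
                 calibration_uv = calibration_uv),
            class = "psg_record")
}

#' @export
print.psg_record <- function(x, ...) {
  cat(sprintf("<psg_record> %d channels x %d samples @ %g Hz (%.1f s)\n",
              length(x$channels), x$n_samples, x$rate, x$n_samples / x$rate))
  invisible(x)
}

#' Simulate a hypnogram with independent sleep scorers
#'
#' Builds a plausible true 30-s epoch stage sequence and derives per-scorer
#' tracks by flipping each epoch to a random different stage with
#' probability `confusion_prob`. The `"normal"` design descends through N1,
#' N2 and N3 and reaches its first REM period `rem_latency_min` after sleep
#' onset, then cycles NREM/REM; the `"narcolepsy"` design (daytime nap with
#' short REM latency) enters REM within about a minute.
#'
#' @param design `"normal"` or `"narcolepsy"`.
#' @param total_min Recording length, minutes.
#' @param rem_latency_min REM latency from sleep onset, minutes (normal
#'   design; default 68).
#' @param sleep_latency_min Wake before sleep onset, minutes.
#' @param rem_period_min,nrem_period_min REM period length and NREM
#'   inter-REM interval, minutes.
#' @param confusion_prob Per-epoch probability a scorer mislabels the epoch.
#' @param n_scorers Number of scorer tracks (<= 3 in the study; default 3).
#' @param seed Optional integer seed.
#' @return A `hypnogram`: list with `epoch_s = 30`, `truth` (stage vector)
#'   and `scorers` (epochs x scorers character matrix).
#' @export
simulate_hypnogram <- function(design = c("normal", "narcolepsy"),
                               total_min = 480, rem_latency_min = 68,
                               sleep_latency_min = 5, rem_period_min = 20,
                               nrem_period_min = 70, confusion_prob = 0.1,
                               n_scorers = 3L, seed = NULL) {
  design <- match.arg(design)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_ep <- max(1L, floor(total_min * 2))
  if (design == "narcolepsy") {
    if (is.null(match.call()$total_min)) n_ep <- 40L # 20-min nap
    truth <- c("W", rep("REM", max(0L, n_ep - 1L)))[seq_len(n_ep)]
  } else {
    w <- max(1L, round(sleep_latency_min * 2))
    pre_rem <- round(rem_latency_min * 2) # epochs from sleep onset to REM
    descent <- c(rep("N1", 4), rep("N2", 20), rep("N3", 30))
    cycle_nrem <- max(2L, round(nrem_period_min * 2))
    cycle_rem <- max(2L, round(rem_period_min * 2))
    first <- c(descent, rep("N2", max(0L, pre_rem - length(descent))))
    first <- first[seq_len(max(1L, pre_rem))]
    truth <- c(rep("W", w), first)
    while (length(truth) < n_ep) {
      truth <- c(truth, rep("REM", cycle_rem),
                 rep("N2", cycle_nrem %/% 2), rep("N3", cycle_nrem %/% 4),
                 rep("N2", cycle_nrem - cycle_nrem %/% 2 - cycle_nrem %/% 4))
    }
    truth <- truth[seq_len(n_ep)]
  }
  scorers <- matrix(rep(truth, n_scorers), ncol = n_scorers)
  if (confusion_prob > 0) {
    for (s in seq_len(n_scorers)) {
      flip <- stats::runif(n_ep) < confusion_prob
      if (any(flip)) {
        scorers[flip, s] <- vapply(truth[flip], function(st) {
          sample(setdiff(.stage_levels, st), 1L)
        }, character(1))
      }
    }
  }
  colnames(scorers) <- paste0("scorer", seq_len(n_scorers))
  structure(list(epoch_s = 30, truth = truth, scorers = scorers,
                 design = design),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d x 30-s epochs, %d scorer track(s), %s design\n",
              length(x$truth), ncol(x$scorers), x$design))
  invisible(x)
}

# one volitional eye movement: ramp-hold-return, unit amplitude
.move_template <- function(n, rate) {
  ramp <- max(1L, round(0.1 * rate))
  n <- max(n, 2L * ramp + 1L)
  c(seq(0, 1, length.out = ramp), rep(1, n - 2L * ramp),
    seq(1, 0, length.out = ramp))
}

# half-sine saccade template, unit amplitude
.saccade_template <- function(n) sin(pi * seq_len(n) / (n + 1))

.add_segment <- function(x, i0, seg) {
  idx <- i0 + seq_along(seg) - 1L
  keep <- idx >= 1L & idx <= length(x)
  x[idx[keep]] <- x[idx[keep]] + seg[keep]
  x
}

#' Render a synthetic polysomnography record with embedded answer signals
#'
#' Builds the eight-channel record for a stimulus schedule plus an answer
#' plan, and returns it together with the exact ground-truth event log.
#' Volitional eye movements are rendered as ramp-hold-return deflections
#' with opposite polarity on the two EOG channels (left movement: `EOG_L`
#' positive, `EOG_R` negative) at `signal_to_background_ratio` times the
#' background saccade amplitude; facial answers as high-frequency EMG burst
#' envelopes on the corrugator/zygomatic channels.
#'
#' @param schedule A `stimulus_schedule` (or its `events` data.frame).
#' @param answer_plan Data.frame with one row per planned response:
#'   `stimulus_index` (row of the schedule), `action` (`"hit"` or `"miss"`),
#'   `answer` (integer, eye answers), `code_kind` (`"LR_COUNT"`/
#'   `"MORSE_GAZE"`/`"MUSCLE"`), `latency_s`, and for muscle answers
#'   `muscle` and `count`. `NULL` means no responses.
#' @param params A [sim_params()] object.
#' @param duration_s Record length; defaults to last stimulus + 30 s.
#' @param hypnogram Optional `hypnogram` controlling stage-dependent
#'   background (chin atonia, saccade presence); default all-REM.
#' @param lucidity Optional data.frame (`onset_s`, `pattern` e.g.
#'   `"LRLRLR"`) of lucidity signals to embed.
#' @param seed Optional integer seed.
#' @return List with `record` (a `psg_record`) and `events` (an `event_log`
#'   data.frame: `type` in stimulus/answer/lucidity, `onset_s`, `detail`,
#'   `stimulus_index`, `amplitude_uv`).
#' @export
render_record <- function(schedule, answer_plan = NULL, params = sim_params(),
                          duration_s = NULL, hypnogram = NULL,
                          lucidity = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  events_df <- if (inherits(schedule, "stimulus_schedule")) schedule$events
               else schedule
  p <- params
  if (is.null(duration_s)) {
    duration_s <- if (nrow(events_df)) max(events_df$onset_s) + 30 else 60
  }
  n <- ceiling(duration_s * p$rate)
  t_of <- function(i) (i - 1L) / p$rate
  i_of <- function(t) floor(t * p$rate) + 1L

  stage_of_sample <- function(i) {
    if (is.null(hypnogram)) return(rep("REM", length(i)))
    ep <- pmin(length(hypnogram$truth), floor(t_of(i) / 30) + 1L)
    hypnogram$truth[ep]
  }
  stages <- stage_of_sample(seq_len(n))
  rem_mask <- stages == "REM"
  w_mask <- stages == "W"

  # EEG: band-colored noise; alpha (10 Hz) in wake, theta (5 Hz) in REM
  tt <- (seq_len(n) - 1L) / p$rate
  mk_eeg <- function() {
    x <- stats::rnorm(n, sd = p$noise_uv)
    x <- x + 0.8 * p$noise_uv * sin(2 * pi * 5 * tt +
                                      stats::runif(1, 0, 2 * pi)) * rem_mask
    x + 1.5 * p$noise_uv * sin(2 * pi * 10 * tt +
                                 stats::runif(1, 0, 2 * pi)) * w_mask
  }
  eeg_f <- mk_eeg(); eeg_c <- mk_eeg(); eeg_o <- mk_eeg()

  # EOG background: noise plus Poisson-arriving conjugate saccades in REM
  eog_l <- stats::rnorm(n, sd = p$noise_uv)
  eog_r <- stats::rnorm(n, sd = p$noise_uv)
  sacc_n <- stats::rpois(1, p$saccade_rate_hz * duration_s)
  if (sacc_n > 0) {
    sacc_t <- sort(stats::runif(sacc_n, 0, duration_s - p$saccade_dur_s))
    tmpl <- .saccade_template(max(2L, round(p$saccade_dur_s * p$rate)))
    for (ts in sacc_t) {
      i0 <- i_of(ts)
      if (!rem_mask[min(i0, n)]) next # saccadic bursts are a REM feature here
      dir <- sample(c(1, -1), 1L)
      eog_l <- .add_segment(eog_l, i0, dir * p$saccade_uv * tmpl)
      eog_r <- .add_segment(eog_r, i0, -dir * p$saccade_uv * tmpl)
    }
  }

  # EMG: chin atonia in REM; facial channels quiescent noise
  chin_sd <- ifelse(rem_mask, p$chin_rem_uv, p$chin_wake_uv)
  emg_chin <- stats::rnorm(n) * chin_sd
  emg_corr <- stats::rnorm(n, sd = p$facial_noise_uv)
  emg_zyg <- stats::rnorm(n, sd = p$facial_noise_uv)

  log <- data.frame(type = character(0), onset_s = numeric(0),
                    detail = character(0), stimulus_index = integer(0),
                    amplitude_uv = numeric(0), stringsAsFactors = FALSE)
  add_log <- function(type, onset, detail, idx = NA_integer_, amp = NA_real_) {
    log <<- rbind(log, data.frame(type = type, onset_s = onset,
                                  detail = detail, stimulus_index = idx,
                                  amplitude_uv = amp, stringsAsFactors = FALSE))
  }
  for (k in seq_len(nrow(events_df))) {
    add_log("stimulus", events_df$onset_s[k], events_df$payload[k], k)
  }

  amp <- p$signal_to_background_ratio * p$saccade_uv
  move_n <- round(p$move_dur_s * p$rate)
  embed_dirs <- function(onset, dirs) {
    t0 <- onset
    for (d in dirs) {
      i0 <- i_of(t0)
      if (i0 + move_n > n) break
      sgn <- if (d == "L") 1 else -1
      tmpl <- .move_template(move_n, p$rate)
      eog_l <<- .add_segment(eog_l, i0, sgn * amp * tmpl)
      eog_r <<- .add_segment(eog_r, i0, -sgn * amp * tmpl)
      t0 <- t0 + p$move_dur_s + p$move_gap_s
    }
  }
  burst_n <- round(p$burst_dur_s * p$rate)
  embed_bursts <- function(onset, muscle_seq) {
    t0 <- onset
    for (m in muscle_seq) {
      i0 <- i_of(t0)
      if (i0 + burst_n > n) break
      idx <- i0:(i0 + burst_n - 1L)
      gain <- p$burst_gain * p$facial_noise_uv
      extra <- stats::rnorm(length(idx)) * gain
      if (m == "ZYGOMATIC") emg_zyg[idx] <<- emg_zyg[idx] + extra
      else emg_corr[idx] <<- emg_corr[idx] + extra
      t0 <- t0 + p$burst_dur_s + p$burst_gap_s
    }
  }

  if (!is.null(lucidity) && nrow(lucidity)) {
    for (k in seq_len(nrow(lucidity))) {
      dirs <- strsplit(lucidity$pattern[k], "")[[1]]
      embed_dirs(lucidity$onset_s[k], dirs)
      add_log("lucidity", lucidity$onset_s[k], lucidity$pattern[k],
              NA_integer_, amp)
    }
  }

  if (!is.null(answer_plan) && nrow(answer_plan)) {
    if (any(answer_plan$stimulus_index < 1L |
              answer_plan$stimulus_index > nrow(events_df))) {
      stop("answer plan references a stimulus absent from the schedule",
           call. = FALSE)
    }
    for (k in seq_len(nrow(answer_plan))) {
      row <- answer_plan[k, ]
      if (!identical(row$action, "hit")) next
      onset <- events_df$onset_s[row$stimulus_index] + row$latency_s
      if (identical(row$code_kind, "MUSCLE")) {
        seq_m <- if (identical(row$muscle, "CORR_THEN_ZYG")) {
          c("CORRUGATOR", "ZYGOMATIC")
        } else rep(row$muscle, row$count)
        embed_bursts(onset, seq_m)
        add_log("answer", onset, paste(seq_m, collapse = "+"),
                row$stimulus_index,
                p$burst_gain * p$facial_noise_uv)
      } else {
        dirs <- encode_answer(row$answer, row$code_kind)
        embed_dirs(onset, dirs)
        add_log("answer", onset, paste(dirs, collapse = ""),
                row$stimulus_index, amp)
      }
    }
  }

  rec <- psg_record(list(EEG_F = eeg_f, EEG_C = eeg_c, EEG_O = eeg_o,
                         EOG_L = eog_l, EOG_R = eog_r, EMG_chin = emg_chin,
                         EMG_corr = emg_corr, EMG_zyg = emg_zyg),
                    rate = p$rate, calibration_uv = p$calibration_uv)
  log <- log[order(log$onset_s), , drop = FALSE]
  rownames(log) <- NULL
  class(log) <- c("event_log", "data.frame")
  list(record = rec, events = log)
}

#' Simulate independent signal raters for one trial
#'
#' Each rater reports the true signal count with probability `p_correct`;
#' otherwise they miscount by one or report no signal. When the truth is no
#' signal, a rater false-alarms a count with probability `p_false_alarm`.
#' Confidence is drawn from `conf_probs` (the classification layer uses
#' only high-confidence ratings).
#'
#' @param truth Integer signal count, or `NA` for no signal. For facial
#'   trials, give `truth_muscle` as well.
#' @param n_raters Number of raters (default 4: three naive raters plus the
#'   experimenter's original rating).
#' @param p_correct Probability a rater reports the truth.
#' @param p_false_alarm Probability of reporting a signal when truth is NA.
#' @param conf_probs Length-3 probability vector over HIGH, MODERATE, LOW.
#' @param truth_muscle Optional muscle label for facial trials.
#' @param seed Optional integer seed.
#' @return Data.frame with `rater`, `count` (integer or NA), `muscle`
#'   (character or NA), `confidence`.
#' @export
simulate_raters <- function(truth, n_raters = 4L, p_correct = 0.9,
                            p_false_alarm = 0.05,
                            conf_probs = c(HIGH = 1, MODERATE = 0, LOW = 0),
                            truth_muscle = NA_character_, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  stopifnot(length(conf_probs) == 3L)
  counts <- integer(n_raters); muscles <- rep(NA_character_, n_raters)
  for (r in seq_len(n_raters)) {
    if (is.na(truth)) {
      if (stats::runif(1) < p_false_alarm) {
        counts[r] <- sample(1:4, 1L)
        muscles[r] <- if (!is.na(truth_muscle)) {
          sample(c("ZYGOMATIC", "CORRUGATOR"), 1L)
        } else NA_character_
      } else counts[r] <- NA_integer_
    } else if (stats::runif(1) < p_correct) {
      counts[r] <- as.integer(truth)
      muscles[r] <- truth_muscle
    } else {
      err <- sample(c("minus", "plus", "none"), 1L)
      counts[r] <- switch(err,
        minus = if (truth > 1L) as.integer(truth - 1L) else NA_integer_,
        plus = as.integer(truth + 1L),
        none = NA_integer_)
      muscles[r] <- if (is.na(counts[r])) NA_character_ else truth_muscle
    }
  }
  conf <- sample(c("HIGH", "MODERATE", "LOW"), n_raters, replace = TRUE,
                 prob = conf_probs)
  data.frame(rater = seq_len(n_raters), count = counts, muscle = muscles,
             confidence = conf, stringsAsFactors = FALSE)
}
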