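#' @title Automated eye-movement and muscle-burst detection
#' @name detect
#' @description
#' A reproducible stand-in for the human signal raters: volitional eye
#' movements are detected on the differential EOG (`EOG_L - EOG_R`, which
#' doubles conjugate deflections and cancels common-mode offsets), grouped
#' into trains and decoded; facial contractions are counted from the
#' RMS envelope of the corrugator/zygomatic EMG.
NULL

#' Detector parameters
#'
#' The amplitude threshold is `threshold_mads` times the MAD-based robust SD
#' of the differential EOG over a `baseline_s` window preceding the analysis
#' window. A deflection must additionally stay beyond threshold for
#' `min_duration_s`: background saccades are brief (~0.1 s) while volitional
#' maximal-scan movements are sustained (~0.5 s), and amplitude alone cannot
#' separate the two from the noise floor.
#'
#' @param threshold_mads Threshold in robust SDs of the baseline (default
#'   2.5).
#' @param baseline_s Baseline length before the window, seconds (default 60).
#' @param min_duration_s Minimum continuous above-threshold duration for an
#'   eye-movement event (default 0.25 s).
#' @param refractory_s Minimum onset-to-onset separation between events
#'   (default 0.3 s).
#' @param train_gap_s Maximum onset gap within one answer train (default
#'   2.0 s).
#' @param emg_rms_s EMG moving-RMS window (default 0.05 s).
#' @param emg_threshold Burst threshold as multiple of baseline RMS
#'   (default 4).
#' @param emg_merge_gap_s Merge bursts separated by less than this
#'   (default 0.25 s).
#' @return A `detector_params` list.
#' @export
detector_params <- function(threshold_mads = 2.5, baseline_s = 60,
                            min_duration_s = 0.25, refractory_s = 0.3,
                            train_gap_s = 2.0, emg_rms_s = 0.05,
                            emg_threshold = 4, emg_merge_gap_s = 0.25) {
  structure(list(threshold_mads = threshold_mads, baseline_s = baseline_s,
                 min_duration_s = min_duration_s, refractory_s = refractory_s,
                 train_gap_s = train_gap_s, emg_rms_s = emg_rms_s,
                 emg_threshold = emg_threshold,
                 emg_merge_gap_s = emg_merge_gap_s),
            class = "detector_params")
}

.check_window <- function(record, window) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  dur <- record$n_samples / record$rate
  if (window[1] < 0 || window[2] > dur + 1e-9) {
    stop(sprintf("window [%g, %g] outside record (0, %g)",
                 window[1], window[2], dur), call. = FALSE)
  }
}

# runs of TRUE in a logical vector -> matrix of (start, end) indices
.runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Detect volitional eye-movement events
#'
#' Thresholds the differential EOG against a robust baseline estimate and
#' returns sustained deflections as lateralized events. A positive
#' differential deflection (left channel up, right channel down) is a
#' leftward movement.
#'
#' @param record A `psg_record` containing `EOG_L` and `EOG_R`.
#' @param window Numeric `(start_s, end_s)` analysis window; must lie inside
#'   the record.
#' @param params A [detector_params()] object.
#' @return Data.frame of events: `onset_s`, `direction` (`"L"`/`"R"`),
#'   `peak_uv`, `duration_s`; zero rows when nothing exceeds threshold.
#'   Attribute `threshold_uv` records the threshold used.
#' @export
detect_eye_movements <- function(record, window,
                                 params = detector_params()) {
  stopifnot(inherits(record, "psg_record"))
  .check_window(record, window)
  p <- params
  rate <- record$rate
  d <- record$channels$EOG_L - record$channels$EOG_R
  i0 <- max(1L, floor(window[1] * rate) + 1L)
  i1 <- min(record$n_samples, ceiling(window[2] * rate))
  b1 <- i0 - 1L
  b0 <- max(1L, b1 - round(p$baseline_s * rate) + 1L)
  baseline <- if (b1 >= b0) d[b0:b1] else d[i0:i1]
  thr <- p$threshold_mads * stats::mad(baseline, constant = 1.4826)
  seg <- d[i0:i1]

  events <- data.frame(onset_s = numeric(0), direction = character(0),
                       peak_uv = numeric(0), duration_s = numeric(0))
  min_len <- round(p$min_duration_s * rate)
  for (sgn in c(1, -1)) {
    mask <- if (sgn > 0) seg > thr else seg < -thr
    if (thr <= 0) mask <- rep(FALSE, length(seg)) # degenerate flat baseline
    runs <- .runs(mask)
    if (!nrow(runs)) next
    keep <- (runs[, 2] - runs[, 1] + 1L) >= min_len
    for (k in which(keep)) {
      idx <- runs[k, 1]:runs[k, 2]
      events <- rbind(events, data.frame(
        onset_s = (i0 + runs[k, 1] - 2L) / rate,
        direction = if (sgn > 0) "L" else "R",
        peak_uv = max(abs(seg[idx])),
        duration_s = length(idx) / rate))
    }
  }
  events <- events[order(events$onset_s), , drop = FALSE]
  if (nrow(events) > 1L) {
    keep <- rep(TRUE, nrow(events))
    last <- events$onset_s[1]
    for (k in 2:nrow(events)) {
      if (events$onset_s[k] - last < p$refractory_s) keep[k] <- FALSE
      else last <- events$onset_s[k]
    }
    events <- events[keep, , drop = FALSE]
  }
  rownames(events) <- NULL
  attr(events, "threshold_uv") <- thr
  events
}

#' Decode an answer from detected eye-movement events
#'
#' Groups events into trains (successive onsets at most `train_gap_s`
#' apart), takes the first train in the window, and decodes it with the
#' answer codec.
#'
#' @param events Output of [detect_eye_movements()].
#' @param code_kind `"LR_COUNT"` or `"MORSE_GAZE"`.
#' @param params A [detector_params()] object (for the train gap).
#' @return Decoded integer count (LR), decoded character (gaze Morse),
#'   `"malformed"`/`"unrecognized"` for undecodable trains, or `NA` when
#'   there are no events.
#' @export
count_answer <- function(events, code_kind = c("LR_COUNT", "MORSE_GAZE"),
                         params = detector_params()) {
  code_kind <- match.arg(code_kind)
  if (is.null(events) || nrow(events) == 0L) return(NA)
  gaps <- diff(events$onset_s)
  train_id <- cumsum(c(1, as.integer(gaps > params$train_gap_s)))
  dirs <- events$direction[train_id == 1L]
  if (code_kind == "LR_COUNT") decode_lr_count(dirs)
  else decode_gaze_morse(dirs)
}

#' Count facial-muscle contraction bursts
#'
#' Computes a moving-RMS envelope of the requested facial EMG channel,
#' thresholds it at a multiple of the pre-window baseline RMS, merges
#' crossings closer than the merge gap, and counts the bursts.
#'
#' @param record A `psg_record`.
#' @param muscle `"ZYGOMATIC"` or `"CORRUGATOR"`.
#' @param window Numeric `(start_s, end_s)` analysis window.
#' @param params A [detector_params()] object.
#' @return Integer burst count (0 when quiescent).
#' @export
detect_contractions <- function(record,
                                muscle = c("ZYGOMATIC", "CORRUGATOR"),
                                window, params = detector_params()) {
  stopifnot(inherits(record, "psg_record"))
  muscle <- match.arg(muscle)
  chan <- switch(muscle, ZYGOMATIC = "EMG_zyg", CORRUGATOR = "EMG_corr")
  if (is.null(record$channels[[chan]])) {
    stop(sprintf("channel %s missing from record", chan), call. = FALSE)
  }
  .check_window(record, window)
  p <- params
  rate <- record$rate
  x <- record$channels[[chan]]
  w <- max(2L, round(p$emg_rms_s * rate))
  env <- sqrt(stats::filter(x^2, rep(1 / w, w), sides = 2))
  env[is.na(env)] <- 0
  i0 <- max(1L, floor(window[1] * rate) + 1L)
  i1 <- min(record$n_samples, ceiling(window[2] * rate))
  b1 <- i0 - 1L
  b0 <- max(1L, b1 - round(p$baseline_s * rate) + 1L)
  base_rms <- if (b1 >= b0) stats::median(env[b0:b1]) else stats::median(env)
  thr <- p$emg_threshold * base_rms
  mask <- env[i0:i1] > thr
  if (thr <= 0) return(0L)
  runs <- .runs(as.vector(mask))
  if (!nrow(runs)) return(0L)
  # merge bursts separated by less than the merge gap
  gap <- round(p$emg_merge_gap_s * rate)
  merged <- 1L
  if (nrow(runs) > 1L) {
    for (k in 2:nrow(runs)) {
      if (runs[k, 1] - runs[k - 1L, 2] > gap) merged <- merged + 1L
    }
  }
  merged
}
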