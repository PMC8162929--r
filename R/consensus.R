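#' @title Multi-rater consensus classification under REM gating
#' @name consensus
#' @description
#' Trials enter the summary only when the 30-s epoch containing the
#' communication attempt was scored REM by at least two of the three
#' independent sleep scorers and the session contained a signal-verified
#' lucid dream (SVLD). Each gated trial is classified from four rater
#' judgments (three naive raters plus the experimenter's original rating)
#' into CORRECT / INCORRECT / AMBIGUOUS / NO_RESPONSE; only high-confidence
#' ratings count, with non-high ratings treated as abstentions against
#' absolute thresholds (at least 3 of 4 raters, or 2 no-response raters).
NULL

.outcomes <- c("CORRECT", "INCORRECT", "AMBIGUOUS", "NO_RESPONSE")

#' Gate a trial on consensus REM sleep and SVLD status
#'
#' @param stage_labels Character vector of exactly 3 scorer stage labels for
#'   the trial's epoch (from `W`, `N1`, `N2`, `N3`, `REM`).
#' @param svld Logical: did the session contain a signal-verified lucid
#'   dream?
#' @return `"INCLUDED"` iff at least 2 of the 3 labels are REM and `svld` is
#'   `TRUE`; otherwise `"EXCLUDED_NOT_REM"` or `"EXCLUDED_NOT_SVLD"` (the REM
#'   criterion is checked first).
#' @export
gate_trial <- function(stage_labels, svld) {
  if (length(stage_labels) != 3L) {
    stop("exactly 3 scorer stage labels are required", call. = FALSE)
  }
  if (!all(stage_labels %in% .stage_levels)) {
    stop("unknown stage label: ",
         paste(setdiff(stage_labels, .stage_levels), collapse = ", "),
         call. = FALSE)
  }
  if (sum(stage_labels == "REM") < 2L) return("EXCLUDED_NOT_REM")
  if (!isTRUE(svld)) return("EXCLUDED_NOT_SVLD")
  "INCLUDED"
}

# keep only high-confidence judgments as usable; thresholds stay absolute
.usable_counts <- function(judgments) {
  stopifnot(is.data.frame(judgments), nrow(judgments) == 4L)
  conf <- judgments$confidence
  if (is.null(conf)) conf <- rep("HIGH", 4L)
  judgments[conf == "HIGH", , drop = FALSE]
}

#' Classify an eye-movement trial from four rater judgments
#'
#' Implements the consensus cascade for eye-movement answers: CORRECT when
#' at least 3 of the 4 raters report the expected count; INCORRECT when at
#' least 3 agree on one specific count different from the expected one;
#' NO_RESPONSE when at least 3 report no signal; AMBIGUOUS when at least 3
#' agree there was a response but not on its count, or when 2 raters
#' thought there was no response; any remaining configuration is AMBIGUOUS.
#' Non-high-confidence ratings are abstentions: they are dropped while the
#' thresholds stay at 3-of-4 (or 2 for the no-response clause).
#'
#' @param expected Expected integer answer count.
#' @param judgments Data.frame of exactly 4 rows with columns `count`
#'   (integer or NA for "no signal") and `confidence` (`"HIGH"`,
#'   `"MODERATE"`, `"LOW"`; missing column means all HIGH).
#' @return One of `"CORRECT"`, `"INCORRECT"`, `"AMBIGUOUS"`,
#'   `"NO_RESPONSE"`.
#' @export
classify_eye_trial <- function(expected, judgments) {
  u <- .usable_counts(judgments)
  counts <- u$count
  n_none <- sum(is.na(counts))
  resp <- counts[!is.na(counts)]
  if (sum(resp == expected) >= 3L) return("CORRECT")
  if (length(resp)) {
    tab <- table(resp)
    wrong <- tab[names(tab) != as.character(expected)]
    if (length(wrong) && max(wrong) >= 3L) return("INCORRECT")
  }
  if (n_none >= 3L) return("NO_RESPONSE")
  if (length(resp) >= 3L) return("AMBIGUOUS") # responses seen, no count consensus
  if (n_none >= 2L) return("AMBIGUOUS")       # two raters saw no response
  "AMBIGUOUS"
}

#' Classify a facial-muscle trial from four rater judgments
#'
#' For the two-channel facial tasks (yes/no, tone and semantic
#' discrimination) the signal is two contractions of one muscle: CORRECT
#' when the majority (at least 3 of 4) agree the expected muscle was
#' contracted the expected number of times (two); INCORRECT when the
#' majority agree the wrong muscle was contracted twice; NO_RESPONSE when
#' the majority agree there were no contractions; a count different from
#' two on the expected muscle, or no agreement, is AMBIGUOUS.
#'
#' @param expected_muscle `"ZYGOMATIC"`, `"CORRUGATOR"` or
#'   `"CORR_THEN_ZYG"`.
#' @param judgments Data.frame of exactly 4 rows with columns `muscle`
#'   (character or NA), `count` (integer or NA) and `confidence`.
#' @param expected_count Expected contraction count (default 2).
#' @return One of `"CORRECT"`, `"INCORRECT"`, `"AMBIGUOUS"`,
#'   `"NO_RESPONSE"`.
#' @export
classify_facial_trial <- function(expected_muscle, judgments,
                                  expected_count = 2L) {
  u <- .usable_counts(judgments)
  seen <- !is.na(u$count) & !is.na(u$muscle)
  key <- ifelse(seen, paste(u$muscle, u$count), NA_character_)
  n_none <- sum(is.na(key))
  expected_key <- paste(expected_muscle, expected_count)
  if (sum(key == expected_key, na.rm = TRUE) >= 3L) return("CORRECT")
  if (any(!is.na(key))) {
    tab <- table(key[!is.na(key)])
    # wrong muscle contracted the expected number of times
    wrong_keys <- names(tab)[grepl(paste0(" ", expected_count, "$"),
                                   names(tab)) &
                               names(tab) != expected_key]
    if (length(wrong_keys) && max(tab[wrong_keys]) >= 3L) return("INCORRECT")
  }
  if (n_none >= 3L) return("NO_RESPONSE")
  "AMBIGUOUS"
}

#' Detect a signal-verified lucid dream in an event log
#'
#' Scans the ground-truth (or reconstructed) event log for a lucidity
#' eye-signal train matching the pre-arranged pattern, and requires the
#' signal to fall inside an epoch scored REM by the scorer consensus
#' (at least 2 of 3) when a hypnogram is supplied.
#'
#' @param events An `event_log` data.frame (columns `type`, `onset_s`,
#'   `detail`).
#' @param hypnogram Optional `hypnogram`; when given, the lucidity signal
#'   must lie in a consensus-REM epoch.
#' @param pattern Pre-arranged lucidity pattern (default `"LRLRLR"`, the
#'   three left-right movements; the Dutch design uses `"LRLR"`).
#' @param require_rem Require the REM gate on the signal itself (default
#'   TRUE).
#' @return Logical flag.
#' @export
detect_svld <- function(events, hypnogram = NULL, pattern = "LRLRLR",
                        require_rem = TRUE) {
  if (is.null(events) || nrow(events) == 0L) return(FALSE)
  luc <- events[events$type == "lucidity" & events$detail == pattern, ,
                drop = FALSE]
  if (!nrow(luc)) return(FALSE)
  if (!require_rem || is.null(hypnogram)) return(TRUE)
  for (t in luc$onset_s) {
    ep <- floor(t / hypnogram$epoch_s) + 1L
    if (ep > nrow(hypnogram$scorers)) next
    if (sum(hypnogram$scorers[ep, ] == "REM") >= 2L) return(TRUE)
  }
  FALSE
}

#' Gate and classify a set of trials
#'
#' Convenience wrapper running [gate_trial()] and the appropriate
#' classifier over a trial table.
#'
#' @param trials Data.frame with one row per trial: `expected` (integer),
#'   `count1`..`count4` (rater counts, NA = no signal), optional
#'   `conf1`..`conf4`, `stage1`..`stage3` (scorer labels), `svld`
#'   (logical), optional `task` and `team`.
#' @return The input with added `gate` and `outcome` columns (`outcome` is
#'   NA for excluded trials).
#' @export
classify_trials <- function(trials) {
  stopifnot(is.data.frame(trials))
  n <- nrow(trials)
  gate <- character(n); outcome <- rep(NA_character_, n)
  has_conf <- all(paste0("conf", 1:4) %in% names(trials))
  for (i in seq_len(n)) {
    gate[i] <- gate_trial(unlist(trials[i, paste0("stage", 1:3)],
                                 use.names = FALSE),
                          trials$svld[i])
    if (gate[i] != "INCLUDED") next
    j <- data.frame(
      count = as.integer(unlist(trials[i, paste0("count", 1:4)],
                                use.names = FALSE)),
      confidence = if (has_conf) {
        as.character(unlist(trials[i, paste0("conf", 1:4)],
                            use.names = FALSE))
      } else rep("HIGH", 4L))
    outcome[i] <- classify_eye_trial(trials$expected[i], j)
  }
  trials$gate <- gate
  trials$outcome <- outcome
  trials
}
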