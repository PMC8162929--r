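#' @title Answer codecs: Morse stimuli, gaze-Morse, LR-count and muscle codes
#' @name codec
#' @description
#' The communication protocols encode experimenter queries as Morse-coded
#' stimulus trains (dots = short flashes/tones, dashes = long ones) and
#' dreamer answers as either gaze Morse (a leftward full-range eye movement
#' is a dot, a rightward one a dash), simple LR-pair counts (LR = 1,
#' LRLR = 2, ...), or counted facial-muscle contractions (zygomatic = yes/up,
#' corrugator = no/down). These functions translate between text, symbol
#' sequences, timed pulse trains and decoded answers.
NULL

# International Morse for the task alphabet: digits 0-9 plus the operator
# letters P ("plus") and M ("minus"). The protocol defines nothing else.
.morse_table <- list(
  "0" = c("DASH", "DASH", "DASH", "DASH", "DASH"),
  "1" = c("DOT", "DASH", "DASH", "DASH", "DASH"),
  "2" = c("DOT", "DOT", "DASH", "DASH", "DASH"),
  "3" = c("DOT", "DOT", "DOT", "DASH", "DASH"),
  "4" = c("DOT", "DOT", "DOT", "DOT", "DASH"),
  "5" = c("DOT", "DOT", "DOT", "DOT", "DOT"),
  "6" = c("DASH", "DOT", "DOT", "DOT", "DOT"),
  "7" = c("DASH", "DASH", "DOT", "DOT", "DOT"),
  "8" = c("DASH", "DASH", "DASH", "DOT", "DOT"),
  "9" = c("DASH", "DASH", "DASH", "DASH", "DOT"),
  "P" = c("DOT", "DASH", "DASH", "DOT"),
  "M" = c("DASH", "DASH")
)

#' Morse code table for the task alphabet
#'
#' @return Named list mapping each of the 12 task characters (digits 0-9,
#'   `"P"` for plus, `"M"` for minus) to its symbol vector of `"DOT"`/`"DASH"`.
#' @export
morse_table <- function() .morse_table

#' Stimulus and answer timing parameters
#'
#' Defaults follow the night-protocol conventions: 300-ms dots, 900-ms
#' dashes, a 300-ms pause after each symbol, a 3000-ms pause between
#' characters, and a 20-s answer window after each problem.
#'
#' @param dot_ms Dot (short stimulus) duration in ms.
#' @param dash_ms Dash (long stimulus) duration in ms.
#' @param intra_gap_ms Pause after each symbol within a character, ms.
#' @param char_gap_ms Pause between characters, ms.
#' @param answer_window_s Response window after each problem, seconds.
#' @return An object of class `timing_params`.
#' @export
timing_params <- function(dot_ms = 300, dash_ms = 900, intra_gap_ms = 300,
                          char_gap_ms = 3000, answer_window_s = 20) {
  vals <- c(dot_ms = dot_ms, dash_ms = dash_ms, intra_gap_ms = intra_gap_ms,
            char_gap_ms = char_gap_ms, answer_window_s = answer_window_s)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all timing parameters must be strictly positive", call. = FALSE)
  }
  if (dash_ms <= dot_ms) stop("dash_ms must exceed dot_ms", call. = FALSE)
  structure(as.list(vals), class = "timing_params")
}

#' Encode a problem string as a Morse sequence
#'
#' Accepts digits, whitespace, the words "plus"/"minus" (any case) and the
#' bare letters P/M. Each digit or operator becomes one Morse character.
#'
#' @param text Problem string, e.g. `"4 minus 0"` or `"9"`.
#' @return A `morse_sequence`: list with `characters` (list of symbol
#'   vectors), `chars` (the character labels) and `source_text`.
#' @examples
#' encode_morse("9")
#' encode_morse("4 minus 0")
#' @export
encode_morse <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- character(0)
  if (nzchar(trimws(text))) {
    tokens <- strsplit(trimws(text), "\\s+")[[1]]
    for (tok in tokens) {
      up <- toupper(tok)
      if (up %in% c("PLUS", "P", "+")) {
        chars <- c(chars, "P")
      } else if (up %in% c("MINUS", "M", "-")) {
        chars <- c(chars, "M")
      } else if (grepl("^[0-9]+$", tok)) {
        chars <- c(chars, strsplit(tok, "")[[1]])
      } else {
        stop(sprintf("unsupported character in Morse encoding: '%s'", tok),
             call. = FALSE)
      }
    }
  }
  structure(list(characters = unname(.morse_table[chars]),
                 chars = chars, source_text = text),
            class = "morse_sequence")
}

#' @export
print.morse_sequence <- function(x, ...) {
  glyph <- vapply(x$characters, function(s) {
    paste(ifelse(s == "DOT", ".", "-"), collapse = "")
  }, character(1))
  cat(sprintf("<morse_sequence> \"%s\": %s\n", x$source_text,
              paste(glyph, collapse = " / ")))
  invisible(x)
}

#' Render a Morse sequence as a timed pulse train
#'
#' Symbols within a character are separated by `intra_gap_ms`; characters by
#' `char_gap_ms`. Total duration is the end of the final pulse (no trailing
#' gap).
#'
#' @param seq A `morse_sequence`.
#' @param timing A `timing_params` object.
#' @return A data.frame with columns `onset_ms`, `duration_ms`, `symbol`,
#'   `char_index`; attribute `total_ms` gives the train duration.
#' @export
pulse_train <- function(seq, timing = timing_params()) {
  stopifnot(inherits(seq, "morse_sequence"), inherits(timing, "timing_params"))
  onset <- numeric(0); dur <- numeric(0); sym <- character(0); ci <- integer(0)
  t <- 0
  for (i in seq_along(seq$characters)) {
    if (i > 1L) t <- t + timing$char_gap_ms
    symbols <- seq$characters[[i]]
    for (j in seq_along(symbols)) {
      if (j > 1L) t <- t + timing$intra_gap_ms
      d <- if (symbols[j] == "DOT") timing$dot_ms else timing$dash_ms
      onset <- c(onset, t); dur <- c(dur, d)
      sym <- c(sym, symbols[j]); ci <- c(ci, i)
      t <- t + d
    }
  }
  out <- data.frame(onset_ms = onset, duration_ms = dur,
                    symbol = sym, char_index = ci)
  attr(out, "total_ms") <- t
  out
}

#' Total duration of a pulse train in milliseconds
#' @param train Output of [pulse_train()].
#' @return Duration in ms (0 for an empty train).
#' @export
pulse_train_duration_ms <- function(train) {
  tot <- attr(train, "total_ms")
  if (is.null(tot)) {
    tot <- if (nrow(train) == 0L) 0 else max(train$onset_ms + train$duration_ms)
  }
  tot
}

.dirs_ok <- function(dirs) {
  is.character(dirs) && all(dirs %in% c("L", "R"))
}

#' Decode a gaze-Morse eye-movement sequence
#'
#' Left movements are dots, right movements dashes. Decoding is restricted
#' to the task alphabet (0-9, P, M); any other pattern — including valid
#' Morse for letters outside the task — returns `"unrecognized"`, treated
#' downstream as a detection failure rather than an answer.
#'
#' @param dirs Character vector of `"L"`/`"R"` directions.
#' @return Single character (`"0"`..`"9"`, `"P"`, `"M"`) or `"unrecognized"`.
#' @examples
#' decode_gaze_morse(c("R", "R", "R", "R", "L")) # "9"
#' @export
decode_gaze_morse <- function(dirs) {
  if (!.dirs_ok(dirs) || length(dirs) == 0L) return("unrecognized")
  pattern <- ifelse(dirs == "L", "DOT", "DASH")
  for (ch in names(.morse_table)) {
    if (identical(unname(.morse_table[[ch]]), as.character(pattern))) return(ch)
  }
  "unrecognized"
}

#' Decode a simple LR-count eye-movement sequence
#'
#' The simple answering code signals the integer n by n left-right pairs
#' (LR = 1, LRLR = 2, ...). The sequence must be a strict alternation
#' starting with L and ending with R; anything else (including a trailing
#' unpaired movement) is `"malformed"`, leaving the ambiguity explicit for
#' the consensus layer.
#'
#' @param dirs Character vector of `"L"`/`"R"` directions.
#' @return Integer count, or the string `"malformed"`.
#' @examples
#' decode_lr_count(c("L", "R", "L", "R")) # 2
#' @export
decode_lr_count <- function(dirs) {
  n <- length(dirs)
  if (!.dirs_ok(dirs) || n == 0L || n %% 2L != 0L) return("malformed")
  if (!all(dirs == rep(c("L", "R"), n %/% 2L))) return("malformed")
  as.integer(n %/% 2L)
}

#' Encode an answer value as an eye-movement sequence
#'
#' Inverse of the decoders: `LR_COUNT` yields n left-right pairs;
#' `MORSE_GAZE` yields the Morse pattern of the digit with dots as L and
#' dashes as R.
#'
#' @param value Integer answer. `LR_COUNT` requires `value >= 1`;
#'   `MORSE_GAZE` requires a digit 0-9.
#' @param code_kind `"LR_COUNT"` or `"MORSE_GAZE"`.
#' @return Character vector of `"L"`/`"R"` directions with attribute
#'   `code_kind`.
#' @examples
#' encode_answer(4, "LR_COUNT")   # L R L R L R L R
#' encode_answer(9, "MORSE_GAZE") # R R R R L
#' @export
encode_answer <- function(value, code_kind = c("LR_COUNT", "MORSE_GAZE")) {
  code_kind <- match.arg(code_kind)
  if (length(value) != 1L || !is.finite(value) || value != round(value)) {
    stop("value must be a single integer", call. = FALSE)
  }
  value <- as.integer(value)
  if (code_kind == "LR_COUNT") {
    if (value < 1L) stop("LR_COUNT answers must be >= 1", call. = FALSE)
    dirs <- rep(c("L", "R"), value)
  } else {
    if (value < 0L || value > 9L) {
      stop("MORSE_GAZE answers must be digits 0-9", call. = FALSE)
    }
    sym <- .morse_table[[as.character(value)]]
    dirs <- ifelse(sym == "DOT", "L", "R")
  }
  structure(as.character(dirs), code_kind = code_kind)
}

#' Facial-muscle answer code
#'
#' The facial response channel uses brief successive contractions of the
#' zygomatic (smile) or corrugator (frown) muscle: two zygomatic
#' contractions mean yes/up, two corrugator contractions no/down, a
#' corrugator followed by a zygomatic contraction "mixed", and counted
#' contractions report tap counts in the tactile task.
#'
#' @param meaning One of `"YES"`, `"NO"`, `"UP"`, `"DOWN"`, `"MIXED"`,
#'   `"COUNT"`.
#' @param count Contraction count; required (and used) only for `"COUNT"`.
#' @return A `muscle_code`: list with `muscle` (`"ZYGOMATIC"`,
#'   `"CORRUGATOR"`, or `"CORR_THEN_ZYG"` for mixed), `contraction_count`
#'   and `meaning`.
#' @export
muscle_code <- function(meaning = c("YES", "NO", "UP", "DOWN", "MIXED", "COUNT"),
                        count = NULL) {
  meaning <- match.arg(meaning)
  out <- switch(meaning,
    YES   = list(muscle = "ZYGOMATIC", contraction_count = 2L),
    UP    = list(muscle = "ZYGOMATIC", contraction_count = 2L),
    NO    = list(muscle = "CORRUGATOR", contraction_count = 2L),
    DOWN  = list(muscle = "CORRUGATOR", contraction_count = 2L),
    MIXED = list(muscle = "CORR_THEN_ZYG", contraction_count = 2L),
    COUNT = {
      if (is.null(count) || count < 1L) {
        stop("COUNT muscle code requires count >= 1", call. = FALSE)
      }
      # tap-count task: identity mapping from tap count to contraction count
      list(muscle = "ZYGOMATIC", contraction_count = as.integer(count))
    })
  out$meaning <- meaning
  structure(out, class = "muscle_code")
}
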