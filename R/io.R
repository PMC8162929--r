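#' @title File formats: hypnogram CSV, EDF waveforms, JSON event logs
#' @name io
#' @description
#' Hypnograms travel as CSV (one row per 30-s epoch, one column per
#' scorer), ground-truth event logs and reports as JSON, waveforms as
#' 16-bit EDF. The EDF writer/reader implements the minimal standard
#' subset (one data record per second, all signals at the record rate).
NULL

#' Write / read a hypnogram as CSV
#'
#' One row per 30-s epoch: `epoch_index` (0-based) plus one column per
#' scorer track; a `truth` column is included when present and restored on
#' read. Stage tokens are validated against `W`, `N1`, `N2`, `N3`, `REM`.
#'
#' @param hyp A `hypnogram`.
#' @param path Output CSV path.
#' @return `write_hypnogram` returns `path` invisibly; `read_hypnogram`
#'   returns a `hypnogram`.
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  df <- data.frame(epoch_index = seq_along(hyp$truth) - 1L)
  df$truth <- hyp$truth
  for (s in seq_len(ncol(hyp$scorers))) {
    df[[colnames(hyp$scorers)[s]]] <- hyp$scorers[, s]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot("epoch_index" %in% names(df))
  stage_cols <- setdiff(names(df), "epoch_index")
  for (cc in stage_cols) {
    bad <- which(!df[[cc]] %in% .stage_levels)
    if (length(bad)) {
      stop(sprintf("unknown stage token '%s' in column %s, row %d",
                   df[[cc]][bad[1]], cc, bad[1]), call. = FALSE)
    }
  }
  scorer_cols <- grep("^scorer", stage_cols, value = TRUE)
  if (!length(scorer_cols)) scorer_cols <- setdiff(stage_cols, "truth")
  scorers <- as.matrix(df[, scorer_cols, drop = FALSE])
  truth <- if ("truth" %in% names(df)) df$truth else scorers[, 1]
  structure(list(epoch_s = 30, truth = truth, scorers = scorers,
                 design = "file"),
            class = "hypnogram")
}

# ---- minimal EDF (European Data Format, 16-bit) ----

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Export a polysomnography record to EDF
#'
#' Writes a standard EDF file: 256-byte header plus per-signal headers,
#' one 1-s data record per second, 16-bit samples scaled per channel to
#' the physical min/max actually present. The record length must be a
#' whole number of seconds.
#'
#' @param record A `psg_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_edf <- function(record, path) {
  stopifnot(inherits(record, "psg_record"))
  if (record$n_samples == 0L) stop("empty record", call. = FALSE)
  rate <- record$rate
  if (abs(rate - round(rate)) > 1e-9) {
    stop("EDF export requires an integer sampling rate", call. = FALSE)
  }
  rate <- as.integer(round(rate))
  n_rec <- record$n_samples / rate
  if (abs(n_rec - round(n_rec)) > 1e-9) {
    stop("EDF export requires a whole number of seconds", call. = FALSE)
  }
  n_rec <- as.integer(round(n_rec))
  ns <- length(record$channels)
  labels <- names(record$channels)

  pmin_ <- vapply(record$channels, min, numeric(1))
  pmax_ <- vapply(record$channels, max, numeric(1))
  flat <- pmax_ - pmin_ < 1e-9
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(.edf_pad(x, width), con,
                                     nchars = width, eos = NULL)
  wr("0", 8)                               # version
  wr("X X X X", 80)                        # patient id (anonymous)
  wr("Startdate X X X X", 80)              # recording id
  wr("01.01.01", 8); wr("00.00.00", 8)     # start date/time
  wr(256L * (1L + ns), 8)                  # header bytes
  wr("", 44)                               # reserved
  wr(n_rec, 8)                             # number of data records
  wr("1", 8)                               # data record duration (s)
  wr(ns, 4)                                # number of signals
  for (l in labels) wr(l, 16)              # labels
  for (i in seq_len(ns)) wr("Simulated", 80)      # transducer
  for (i in seq_len(ns)) wr("uV", 8)              # physical dimension
  for (i in seq_len(ns)) wr(format(pmin_[i], digits = 8), 8)
  for (i in seq_len(ns)) wr(format(pmax_[i], digits = 8), 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)               # prefiltering
  for (i in seq_len(ns)) wr(rate, 8)              # samples per record
  for (i in seq_len(ns)) wr("", 32)               # reserved

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * rate + 1L):(r * rate)
    for (i in seq_len(ns)) {
      dig <- round((record$channels[[i]][idx] - pmin_[i]) * scale[i]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [export_edf()]
#'
#' Supports the subset the writer emits: equal per-signal rates, 1-s data
#' records.
#'
#' @param path EDF file path.
#' @return A `psg_record`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  stopifnot(length(unique(spr)) == 1L)
  rate <- spr[1] / rec_dur

  channels <- stats::setNames(
    lapply(seq_len(ns), function(i) numeric(n_rec * spr[i])), labels)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      phys <- (dig - dmin[i]) * (pmax_[i] - pmin_[i]) /
        (dmax[i] - dmin[i]) + pmin_[i]
      channels[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <- phys
    }
  }
  psg_record(channels, rate = rate)
}

#' Write / read a ground-truth event log as JSON
#'
#' @param events An `event_log` data.frame.
#' @param path JSON path.
#' @return `write_event_log` returns `path` invisibly; `read_event_log`
#'   returns the `event_log`.
#' @export
write_event_log <- function(events, path) {
  jsonlite::write_json(as.data.frame(events), path, auto_unbox = FALSE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  df <- jsonlite::fromJSON(path)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  class(df) <- c("event_log", "data.frame")
  df
}

#' Serialize a stimulus schedule to JSON
#'
#' @param schedule A `stimulus_schedule`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  jsonlite::write_json(
    list(session_design = schedule$session_design, events = schedule$events),
    path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

# ---- run configuration (YAML) ----

.default_config <- function() {
  list(design = "usa_tlr", seed = 1L,
       timing = unclass(timing_params()),
       detector = unclass(detector_params()),
       simulator = unclass(sim_params()),
       raters = list(n_raters = 4L, p_correct = 0.9, p_false_alarm = 0.05),
       output = list(dir = "."))
}

#' Read and validate a run configuration
#'
#' YAML configuration with sections `design`, `seed`, `timing`, `detector`,
#' `simulator`, `raters`, `output`; values override the package defaults.
#' Unknown keys (at top level or within a section) are rejected.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- .default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    user <- yaml::read_yaml(path)
    if (!is.list(user)) stop("config must be a YAML mapping", call. = FALSE)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad)) {
      stop("unknown config key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    for (k in names(user)) {
      if (is.list(cfg[[k]]) && is.list(user[[k]])) {
        bad2 <- setdiff(names(user[[k]]), names(cfg[[k]]))
        if (length(bad2)) {
          stop(sprintf("unknown config key(s) under %s: %s", k,
                       paste(bad2, collapse = ", ")), call. = FALSE)
        }
        cfg[[k]][names(user[[k]])] <- user[[k]]
      } else {
        cfg[[k]] <- user[[k]]
      }
    }
  }
  class(cfg) <- "run_config"
  cfg
}

# stable hash of a config for run logs
.config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA),
             tmp)
  unname(tools::md5sum(tmp))
}
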