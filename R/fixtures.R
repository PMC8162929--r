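#' @title Packaged published outcome tables
#' @name fixtures
#' @description
#' The package ships the published per-task outcome table, the session
#' funnel (sessions with communication attempts, with REM, with
#' signal-verified lucid dreaming) and the non-lucid control counts as
#' plain-text fixtures, so the aggregate analyses can be replicated
#' without any external data.
NULL

#' Path to a packaged fixture file
#' @param name File name under `extdata`.
#' @return Absolute path.
#' @export
dreamlink_fixture <- function(name) {
  p <- system.file("extdata", name, package = "dreamlink")
  if (!nzchar(p)) stop("fixture not found: ", name, call. = FALSE)
  p
}

#' Load the per-task outcome fixture
#' @return Data.frame with `team`, `task`, `correct`, `incorrect`,
#'   `ambiguous`, `no_response` rows (one per team/task).
#' @export
load_outcome_fixture <- function() {
  utils::read.csv(dreamlink_fixture("outcomes_by_task.csv"),
                  stringsAsFactors = FALSE)
}

#' Load the session-funnel fixture
#' @return Data.frame with per-team `participants`, `sessions_twc`,
#'   `sessions_rem`, `sessions_svld`, `trials_twc`.
#' @export
load_session_fixture <- function() {
  utils::read.csv(dreamlink_fixture("session_funnel.csv"),
                  stringsAsFactors = FALSE)
}

#' Load the non-lucid control-trial fixture
#' @return List with `per_team` trial counts, the pooled `outcomes`, and
#'   the facial `sham` control (marker and response counts).
#' @export
load_control_fixture <- function() {
  jsonlite::fromJSON(dreamlink_fixture("nonlucid_controls.json"))
}

#' Session funnel summary
#'
#' Aggregates the per-team session table: sessions with two-way
#' communication attempts, how many reached REM sleep, how many contained a
#' signal-verified lucid dream, and the lucidity-signal rate among REM
#' sessions (rounded to the nearest percent).
#'
#' @param sessions Data.frame as returned by [load_session_fixture()].
#' @return List with `n_twc`, `n_rem`, `n_svld`, `n_trials`, and
#'   `pct_svld` (percent of REM-reaching attempt sessions that produced a
#'   lucidity signal, rounded to the nearest percent).
#' @export
session_funnel <- function(sessions = load_session_fixture()) {
  n_twc <- sum(sessions$sessions_twc)
  n_rem <- sum(sessions$sessions_rem)
  n_svld <- sum(sessions$sessions_svld)
  list(n_twc = n_twc, n_rem = n_rem, n_svld = n_svld,
       n_trials = sum(sessions$trials_twc),
       pct_svld = round(100 * n_svld / n_rem))
}
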