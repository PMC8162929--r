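#' @title Outcome aggregation, agreement and chance-level analyses
#' @name stats_module
#' @description
#' Aggregates classified trials into per-task and total outcome tables with
#' percentages, computes Fleiss' kappa for inter-scorer agreement, and runs
#' the chance-level controls: a Fisher exact comparison of response rates in
#' lucid versus non-lucid REM communication attempts, and of stimulation
#' versus sham-marker facial contractions.
NULL

# round half up to `digits` decimals (sprintf/round use banker's rounding)
.round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Summarize trial outcomes into an outcome table
#'
#' Produces the per-task rows and a total row: trial counts per outcome and
#' percentages of the row total, rounded half-up to one decimal.
#'
#' @param trials Either a classified trial data.frame (with `outcome` and
#'   optionally `team`/`task` columns; excluded trials, `outcome` NA, are
#'   dropped), or a pre-tabulated data.frame with columns `team`, `task`,
#'   `correct`, `incorrect`, `ambiguous`, `no_response`.
#' @return A `session_summary` data.frame: `team`, `task`, `n_trials`,
#'   `correct`, `incorrect`, `ambiguous`, `no_response`, plus `pct_*`
#'   percentage columns; the final row is the total. Zero trials yield a
#'   zero-row summary.
#' @export
summarize_trials <- function(trials) {
  stopifnot(is.data.frame(trials))
  cat_cols <- c("correct", "incorrect", "ambiguous", "no_response")
  if (all(cat_cols %in% names(trials))) {
    tab <- trials
    if (is.null(tab$team)) tab$team <- ""
    if (is.null(tab$task)) tab$task <- ""
    tab <- tab[, c("team", "task", cat_cols)]
  } else {
    stopifnot("outcome" %in% names(trials))
    kept <- trials[!is.na(trials$outcome), , drop = FALSE]
    if (!nrow(kept)) {
      out <- data.frame(team = character(0), task = character(0),
                        n_trials = integer(0))
      for (cc in cat_cols) {
        out[[cc]] <- integer(0); out[[paste0("pct_", cc)]] <- numeric(0)
      }
      class(out) <- c("session_summary", "data.frame")
      return(out)
    }
    team <- if (is.null(kept$team)) rep("", nrow(kept)) else kept$team
    task <- if (is.null(kept$task)) rep("", nrow(kept)) else kept$task
    grp <- paste(team, task, sep = "\r")
    rows <- lapply(unique(grp), function(g) {
      sel <- kept$outcome[grp == g]
      data.frame(team = team[grp == g][1], task = task[grp == g][1],
                 correct = sum(sel == "CORRECT"),
                 incorrect = sum(sel == "INCORRECT"),
                 ambiguous = sum(sel == "AMBIGUOUS"),
                 no_response = sum(sel == "NO_RESPONSE"))
    })
    tab <- do.call(rbind, rows)
  }
  tab$n_trials <- as.integer(rowSums(tab[, cat_cols]))
  total <- data.frame(team = "Total", task = "",
                      correct = as.integer(sum(tab$correct)),
                      incorrect = as.integer(sum(tab$incorrect)),
                      ambiguous = as.integer(sum(tab$ambiguous)),
                      no_response = as.integer(sum(tab$no_response)),
                      n_trials = as.integer(sum(tab$n_trials)))
  out <- rbind(tab[, names(total)], total)
  for (cc in cat_cols) {
    out[[paste0("pct_", cc)]] <-
      ifelse(out$n_trials > 0,
             .round_half_up(100 * out[[cc]] / out$n_trials, 1), NA_real_)
  }
  out <- out[, c("team", "task", "n_trials", cat_cols,
                 paste0("pct_", cat_cols))]
  rownames(out) <- NULL
  class(out) <- c("session_summary", "data.frame")
  out
}

#' Fleiss' kappa for a fixed number of raters
#'
#' Chance-corrected agreement for `n` raters assigning each of `N` subjects
#' to one of `k` categories: `kappa = (Pbar - Pe) / (1 - Pe)` where `Pbar`
#' is the mean per-subject pairwise agreement and `Pe` the chance agreement
#' from the marginal category proportions.
#'
#' @param m Integer matrix, subjects x categories; `m[i, j]` is the number
#'   of raters assigning subject `i` to category `j`. Row sums must be
#'   equal (the common rater count) and at least 2; at least 2 subjects.
#' @return Kappa value. When every rating falls in a single category
#'   (`Pe = 1`), agreement is perfect by construction and 1.0 is returned.
#' @export
fleiss_kappa <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 subjects", call. = FALSE)
  n_r <- unique(rowSums(m))
  if (length(n_r) != 1L) {
    stop("all subjects must have the same number of ratings", call. = FALSE)
  }
  n <- n_r[1]
  if (n < 2L) stop("need at least 2 raters", call. = FALSE)
  N <- nrow(m)
  p_j <- colSums(m) / (N * n)
  p_i <- (rowSums(m^2) - n) / (n * (n - 1))
  p_bar <- mean(p_i)
  p_e <- sum(p_j^2)
  if (1 - p_e < .Machine$double.eps^0.5) {
    if (p_bar >= 1 - .Machine$double.eps^0.5) return(1.0)
    stop("degenerate category marginals: chance agreement is 1",
         call. = FALSE)
  }
  (p_bar - p_e) / (1 - p_e)
}

#' 2x2 contingency table for response analyses
#'
#' @param a,b Responses / no-responses under the first condition.
#' @param c,d Responses / no-responses under the second condition.
#' @return A 2x2 integer matrix with dimnames.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  v <- c(a, b, c, d)
  if (any(v < 0) || any(v != round(v))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  matrix(as.integer(v), nrow = 2, byrow = TRUE,
         dimnames = list(condition = c("cond1", "cond2"),
                         response = c("response", "none")))
}

#' Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric test. The one-sided (`"greater"`) alternative —
#' more responses under the first condition — is the default, matching the
#' directional chance-level claims; `"two.sided"` sums all tables with
#' probability not exceeding the observed one.
#'
#' @param table 2x2 matrix (e.g. from [contingency_2x2()]).
#' @param sided `"greater"`, `"less"` or `"two.sided"`.
#' @return The exact p-value.
#' @export
fisher_exact <- function(table, sided = c("greater", "less", "two.sided")) {
  sided <- match.arg(sided)
  stopifnot(is.matrix(table), all(dim(table) == 2L))
  a <- table[1, 1]
  m <- sum(table[1, ]); n2 <- sum(table[2, ]); k <- sum(table[, 1])
  lo <- max(0L, k - n2); hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, n2, k)
  switch(sided,
    greater = sum(dens[support >= a]),
    less = sum(dens[support <= a]),
    two.sided = sum(dens[dens <= stats::dhyper(a, m, n2, k) * (1 + 1e-7)]))
}

#' Chance-level control analyses
#'
#' Builds both control contingency tables and their Fisher exact p-values:
#' (1) response rate during communication attempts in lucid versus
#' non-lucid REM sleep, and (2) facial contractions after stimulation
#' versus after sham markers placed in stimulation-free periods.
#'
#' @param lucid Named counts for lucid-REM attempts: `correct`,
#'   `incorrect`, `ambiguous`, `no_response`.
#' @param nonlucid Same four counts for non-lucid REM attempts.
#' @param sham Optional list for the facial control: `stim_responses`,
#'   `stim_none`, `sham_markers`, `sham_responses` (default 0).
#' @param response_def `"any"` counts correct + incorrect + ambiguous as a
#'   response; `"correct_only"` counts correct responses only.
#' @return A `chance_report` list: `lucid_table`, `lucid_p`, and when
#'   `sham` is given, `sham_table`, `sham_p`; plus the response definition
#'   and rates.
#' @export
chance_analyses <- function(lucid, nonlucid, sham = NULL,
                            response_def = c("any", "correct_only")) {
  response_def <- match.arg(response_def)
  need <- c("correct", "incorrect", "ambiguous", "no_response")
  stopifnot(all(need %in% names(lucid)), all(need %in% names(nonlucid)))
  n_resp <- function(x) {
    if (response_def == "any") {
      x[["correct"]] + x[["incorrect"]] + x[["ambiguous"]]
    } else x[["correct"]]
  }
  n_none <- function(x) sum(unlist(x[need])) - n_resp(x)
  lucid_tab <- contingency_2x2(n_resp(lucid), n_none(lucid),
                               n_resp(nonlucid), n_none(nonlucid))
  out <- list(response_def = response_def,
              lucid_table = lucid_tab,
              lucid_rate = n_resp(lucid) / sum(unlist(lucid[need])),
              nonlucid_rate = n_resp(nonlucid) / sum(unlist(nonlucid[need])),
              lucid_p = fisher_exact(lucid_tab, "greater"))
  if (!is.null(sham)) {
    sham_resp <- sham$sham_responses %||% 0L
    sham_tab <- contingency_2x2(sham$stim_responses,
                                sham$stim_none,
                                sham_resp,
                                sham$sham_markers - sham_resp)
    out$sham_table <- sham_tab
    out$sham_p <- fisher_exact(sham_tab, "greater")
  }
  class(out) <- "chance_report"
  out
}

#' @export
print.chance_report <- function(x, ...) {
  cat(sprintf(
    "<chance_report> responses (%s): lucid %.3f vs non-lucid %.3f, Fisher p = %.3g\n",
    x$response_def, x$lucid_rate, x$nonlucid_rate, x$lucid_p))
  if (!is.null(x$sham_p)) {
    cat(sprintf("  stimulation vs sham markers: Fisher p = %.3g\n", x$sham_p))
  }
  invisible(x)
}
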