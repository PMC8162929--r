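test_that("summarize_trials reproduces the published total row", {
  s <- summarize_trials(load_outcome_fixture())
  tot <- s[s$team == "Total", ]
  expect_identical(tot$n_trials, 158L)
  expect_identical(tot$correct, 29L)
  expect_identical(tot$incorrect, 5L)
  expect_identical(tot$ambiguous, 28L)
  expect_identical(tot$no_response, 96L)
  expect_identical(tot$pct_correct, 18.4)
  expect_identical(tot$pct_incorrect, 3.2)
  expect_identical(tot$pct_ambiguous, 17.7)
  expect_identical(tot$pct_no_response, 60.8)
})

test_that("summaries conserve counts and percentages recompose", {
  s <- summarize_trials(load_outcome_fixture())
  expect_true(all(s$correct + s$incorrect + s$ambiguous + s$no_response ==
                    s$n_trials))
  pct_sums <- rowSums(s[, c("pct_correct", "pct_incorrect", "pct_ambiguous",
                            "pct_no_response")])
  expect_true(all(pct_sums >= 99.8 & pct_sums <= 100.2))
})

test_that("summarize_trials handles outcome-labeled trials and edge cases", {
  one <- data.frame(outcome = "CORRECT")
  s <- summarize_trials(one)
  expect_identical(s$n_trials[s$team == "Total"], 1L)
  expect_identical(s$pct_correct[s$team == "Total"], 100.0)

  # simulated block: counts sum to n
  set.seed(5)
  many <- data.frame(outcome = sample(c("CORRECT", "INCORRECT", "AMBIGUOUS",
                                        "NO_RESPONSE"), 1000, replace = TRUE))
  sm <- summarize_trials(many)
  expect_identical(sm$n_trials[sm$team == "Total"], 1000L)

  # zero trials: empty summary, no division error
  empty <- summarize_trials(data.frame(outcome = character(0)))
  expect_identical(nrow(empty), 0L)
})

test_that("Fleiss' kappa matches hand-computed values", {
  # perfect agreement
  expect_identical(fleiss_kappa(matrix(c(3, 0, 0, 3), 2, byrow = TRUE)), 1.0)
  expect_identical(fleiss_kappa(matrix(c(3, 0, 3, 0), 2, byrow = TRUE)), 1.0)
  # hand-computed: Pbar = 2/3, Pe = 1/2 -> kappa = 1/3
  m <- matrix(c(2, 1, 1, 2, 3, 0, 0, 3), ncol = 2, byrow = TRUE)
  expect_equal(fleiss_kappa(m), 1 / 3)
  expect_error(fleiss_kappa(matrix(c(3, 0), 1)), "2 subjects")
  expect_error(fleiss_kappa(matrix(c(3, 0, 2, 0), 2, byrow = TRUE)),
               "same number")
})

test_that("Fleiss' kappa agrees with an independent pairwise-agreement oracle", {
  # oracle: brute-force enumeration of agreeing ordered rater pairs per
  # subject, chance-corrected with the marginal category shares
  oracle <- function(m) {
    n <- rowSums(m)[1]
    agree <- mean(apply(m, 1, function(r) {
      labels <- rep(seq_along(r), r)
      pairs <- expand.grid(a = seq_len(n), b = seq_len(n))
      pairs <- pairs[pairs$a != pairs$b, ]
      mean(labels[pairs$a] == labels[pairs$b])
    }))
    pj <- colSums(m) / sum(m)
    (agree - sum(pj^2)) / (1 - sum(pj^2))
  }
  set.seed(12)
  for (i in 1:20) {
    m <- t(stats::rmultinom(8, size = 4, prob = stats::runif(3, 0.2, 1)))
    if (max(colSums(m)) == sum(m)) next # degenerate single category
    expect_equal(fleiss_kappa(m), oracle(m))
  }
})

test_that("Fleiss' kappa is ~0 for independent uniform ratings", {
  set.seed(13)
  m <- t(stats::rmultinom(1000, size = 3, prob = rep(1 / 3, 3)))
  expect_lt(abs(fleiss_kappa(m)), 0.05)
})

test_that("Fisher exact matches enumeration and stats::fisher.test", {
  # balanced table: upper tail P(X >= 1) = 1 - 1/6 = 5/6
  expect_equal(fisher_exact(contingency_2x2(1, 1, 1, 1), "greater"), 5 / 6)
  # perfect diagonal 5/5: p = 1/choose(10,5) = 1/252
  expect_equal(fisher_exact(contingency_2x2(5, 0, 0, 5), "greater"), 1 / 252)
  set.seed(14)
  for (i in 1:25) {
    tab <- matrix(stats::rpois(4, 8), 2)
    for (sided in c("greater", "less", "two.sided")) {
      expect_equal(fisher_exact(tab, sided),
                   stats::fisher.test(tab, alternative = sided)$p.value,
                   tolerance = 1e-10, label = paste(sided, toString(tab)))
    }
  }
})

test_that("Fisher p decreases as diagonal association strengthens", {
  # fixed margins 20/20, shift mass onto the diagonal
  p <- vapply(0:10, function(k) {
    fisher_exact(contingency_2x2(10 + k, 10 - k, 10 - k, 10 + k), "greater")
  }, numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("chance analyses reproduce the control contrasts", {
  ctrl <- load_control_fixture()
  expect_identical(sum(unlist(ctrl$per_team)), 379L)
  expect_identical(unname(unlist(ctrl$outcomes)), c(1L, 1L, 11L, 366L))

  lucid <- list(correct = 29, incorrect = 5, ambiguous = 28,
                no_response = 96)
  rep <- chance_analyses(lucid, ctrl$outcomes,
                         sham = list(stim_responses = 62, stim_none = 96,
                                     sham_markers = ctrl$sham$markers,
                                     sham_responses = ctrl$sham$responses))
  expect_identical(rep$lucid_table[1, 1], 62L)  # 29 + 5 + 28 responses
  expect_identical(rep$lucid_table[2, 1], 13L)  # 1 + 1 + 11
  expect_identical(rep$lucid_table[2, 2], 366L)
  expect_lt(rep$lucid_p, 0.001)
  expect_identical(rep$sham_table[2, ], c(response = 0L, none = 28L))
  expect_lt(rep$sham_p, 0.001)

  # correct-only definition also clears the bound
  rep2 <- chance_analyses(lucid, ctrl$outcomes,
                          response_def = "correct_only")
  expect_identical(rep2$lucid_table[1, 1], 29L)
  expect_lt(rep2$lucid_p, 0.001)
})

test_that("under a true null the lucid-vs-nonlucid p-value is well calibrated", {
  # simulated null: same response probability in both arms; the exact test
  # must be conservative (P(p <= a) <= a)
  set.seed(15)
  ps <- replicate(200, {
    resp_l <- stats::rbinom(1, 40, 0.15)
    resp_n <- stats::rbinom(1, 60, 0.15)
    fisher_exact(contingency_2x2(resp_l, 40 - resp_l, resp_n, 60 - resp_n),
                 "greater")
  })
  for (a in c(0.05, 0.1, 0.25)) {
    expect_lte(mean(ps <= a), a + 3 * sqrt(a * (1 - a) / 200))
  }
  expect_gt(mean(ps), 0.35) # roughly uniform, not collapsed near 0
})
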