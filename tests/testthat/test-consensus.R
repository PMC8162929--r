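test_that("REM gating requires 2-of-3 scorers and SVLD", {
  expect_identical(gate_trial(c("REM", "REM", "W"), TRUE), "INCLUDED")
  expect_identical(gate_trial(c("REM", "W", "W"), TRUE), "EXCLUDED_NOT_REM")
  expect_identical(gate_trial(c("REM", "REM", "REM"), FALSE),
                   "EXCLUDED_NOT_SVLD")
  expect_error(gate_trial(c("REM", "REM"), TRUE), "exactly 3")
  expect_error(gate_trial(c("REM", "REM", "R1"), TRUE), "R1")
})

test_that("eye-trial classification follows the consensus cascade", {
  cases <- list(
    list(counts = c(2, 2, 2, 2), exp = 2, out = "CORRECT"),
    list(counts = c(2, 2, 2, 5), exp = 2, out = "CORRECT"),
    list(counts = c(3, 3, 3, 1), exp = 2, out = "INCORRECT"),
    list(counts = c(NA, NA, NA, 2), exp = 2, out = "NO_RESPONSE"),
    list(counts = c(NA, NA, NA, NA), exp = 2, out = "NO_RESPONSE"),
    list(counts = c(2, 3, NA, NA), exp = 2, out = "AMBIGUOUS"),
    list(counts = c(2, 3, 4, 5), exp = 2, out = "AMBIGUOUS"),
    # 2-2 split between two distinct counts -> ambiguous
    list(counts = c(2, 2, 3, 3), exp = 2, out = "AMBIGUOUS"))
  for (cs in cases) {
    expect_identical(classify_eye_trial(cs$exp, judgments(cs$counts)),
                     cs$out,
                     label = paste(cs$counts, collapse = ","))
  }
})

test_that("non-high-confidence ratings abstain but thresholds stay absolute", {
  # 3 HIGH matching counts + 1 LOW: still correct
  expect_identical(
    classify_eye_trial(2, judgments(c(2, 2, 2, 9),
                                    c("HIGH", "HIGH", "HIGH", "LOW"))),
    "CORRECT")
  # only 2 usable matches (one abstention): cannot reach 3-of-4
  expect_identical(
    classify_eye_trial(2, judgments(c(2, 2, 2, 4),
                                    c("HIGH", "HIGH", "MODERATE", "HIGH"))),
    "AMBIGUOUS")
  # 2 usable no-response judgments trigger the ambiguity clause
  expect_identical(
    classify_eye_trial(2, judgments(c(NA, NA, 2, 2),
                                    c("HIGH", "HIGH", "LOW", "LOW"))),
    "AMBIGUOUS")
})

test_that("facial-trial classification follows the majority cascade", {
  expect_identical(
    classify_facial_trial("ZYGOMATIC",
                          facial_judgments(c("ZYGOMATIC", "ZYGOMATIC",
                                             "ZYGOMATIC", NA),
                                           c(2, 2, 2, NA))),
    "CORRECT")
  expect_identical(
    classify_facial_trial("ZYGOMATIC",
                          facial_judgments(c("CORRUGATOR", "CORRUGATOR",
                                             "CORRUGATOR", NA),
                                           c(2, 2, 2, NA))),
    "INCORRECT")
  # expected muscle contracted a count other than two -> ambiguous
  expect_identical(
    classify_facial_trial("ZYGOMATIC",
                          facial_judgments(c("ZYGOMATIC", "ZYGOMATIC",
                                             "ZYGOMATIC", NA),
                                           c(1, 1, 1, NA))),
    "AMBIGUOUS")
  expect_identical(
    classify_facial_trial("ZYGOMATIC",
                          facial_judgments(rep(NA_character_, 4),
                                           rep(NA_integer_, 4))),
    "NO_RESPONSE")
})

test_that("SVLD detection needs the pre-arranged pattern in consensus REM", {
  hyp <- simulate_hypnogram("narcolepsy", confusion_prob = 0, seed = 1)
  in_rem <- data.frame(type = "lucidity", onset_s = 120, detail = "LRLRLR",
                       stimulus_index = NA_integer_, amplitude_uv = 75)
  expect_true(detect_svld(in_rem, hyp))
  # epoch 1 is wake: gated out
  in_wake <- transform(in_rem, onset_s = 10)
  expect_false(detect_svld(in_wake, hyp))
  # empty log, wrong pattern
  expect_false(detect_svld(in_rem[0, ], hyp))
  expect_false(detect_svld(transform(in_rem, detail = "LRLR"), hyp))
  expect_true(detect_svld(transform(in_rem, detail = "LRLR"), hyp,
                          pattern = "LRLR"))
  # without a hypnogram (or with require_rem = FALSE) the pattern suffices
  expect_true(detect_svld(in_wake, hyp, require_rem = FALSE))
})

test_that("classification is exhaustive and permutation-invariant (fuzz)", {
  set.seed(99)
  pool <- c(NA, 1:9)
  for (i in 1:2000) {
    counts <- sample(pool, 4L, replace = TRUE)
    expected <- sample(1:9, 1L)
    out <- classify_eye_trial(expected, judgments(counts))
    expect_true(out %in% c("CORRECT", "INCORRECT", "AMBIGUOUS",
                           "NO_RESPONSE"))
    perm <- sample(4L)
    expect_identical(classify_eye_trial(expected, judgments(counts[perm])),
                     out)
  }
})

test_that("classify_trials conserves counts and respects gates", {
  set.seed(7)
  n <- 60
  trials <- data.frame(
    expected = sample(1:4, n, replace = TRUE),
    stage1 = sample(c("REM", "W"), n, replace = TRUE, prob = c(0.8, 0.2)),
    stage2 = sample(c("REM", "W"), n, replace = TRUE, prob = c(0.8, 0.2)),
    stage3 = sample(c("REM", "W"), n, replace = TRUE, prob = c(0.8, 0.2)),
    svld = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.8, 0.2)))
  for (k in 1:4) trials[[paste0("count", k)]] <- trials$expected
  out <- classify_trials(trials)
  gated <- out$gate == "INCLUDED"
  # conservation: every gated trial gets exactly one outcome
  expect_identical(sum(!is.na(out$outcome)), sum(gated))
  # perfect raters: all gated trials correct
  expect_true(all(out$outcome[gated] == "CORRECT"))
  expect_true(all(is.na(out$outcome[!gated])))
})
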