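test_that("narcolepsy hypnogram reaches REM within ~1 min", {
  hyp <- simulate_hypnogram("narcolepsy", confusion_prob = 0, seed = 1)
  expect_lte(which(hyp$truth == "REM")[1], 2L)
  expect_identical(length(hyp$truth), 40L) # 20-min nap
})

test_that("normal hypnogram has the configured REM latency", {
  hyp <- simulate_hypnogram("normal", total_min = 180, rem_latency_min = 68,
                            sleep_latency_min = 5, confusion_prob = 0,
                            seed = 2)
  first_rem <- which(hyp$truth == "REM")[1]
  sleep_onset <- which(hyp$truth != "W")[1]
  expect_equal((first_rem - sleep_onset) / 2, 68, tolerance = 0.02)
  expect_true(all(hyp$truth %in% c("W", "N1", "N2", "N3", "REM")))
})

test_that("scorer tracks reproduce truth exactly at zero confusion", {
  hyp <- simulate_hypnogram("normal", total_min = 60, confusion_prob = 0,
                            seed = 3)
  for (s in 1:3) expect_identical(unname(hyp$scorers[, s]), hyp$truth)
})

test_that("scorer disagreement rate matches the confusion probability", {
  hyp <- simulate_hypnogram("normal", total_min = 5000 / 2,
                            confusion_prob = 0.1, n_scorers = 2L, seed = 4)
  dis <- mean(hyp$scorers != hyp$truth)
  expect_equal(dis, 0.1, tolerance = 0.1) # binomial, n = 10,000 epochs
  expect_lt(abs(dis - 0.1), 0.01)
})

test_that("render_record embeds planned answers with exact ground truth", {
  sim <- render_answer_trial(2, seed = 21, latency_s = 3)
  ans <- sim$events[sim$events$type == "answer", ]
  expect_identical(nrow(ans), 1L)
  expect_identical(ans$onset_s, 73)
  expect_identical(ans$detail, "LRLR")
  expect_identical(ans$stimulus_index, 1L)
  # conservation: every answer maps to exactly one schedule stimulus
  expect_true(all(ans$stimulus_index %in%
                    which(sim$events$type == "stimulus")))
})

test_that("a miss plan embeds no answer signals", {
  sched <- make_schedule(70, expected = 2)
  plan <- data.frame(stimulus_index = 1L, action = "miss", answer = 2L,
                     code_kind = "LR_COUNT", latency_s = 3)
  sim <- render_record(sched, plan, params = sim_params(rate = test_rate),
                       duration_s = 100, seed = 22)
  expect_identical(sum(sim$events$type == "answer"), 0L)
})

test_that("answer plan referencing an absent stimulus is rejected", {
  sched <- make_schedule(70)
  plan <- data.frame(stimulus_index = 2L, action = "hit", answer = 2L,
                     code_kind = "LR_COUNT", latency_s = 3)
  expect_error(render_record(sched, plan,
                             params = sim_params(rate = test_rate),
                             duration_s = 100, seed = 1),
               "absent")
})

test_that("embedded signals dominate background EOG at ratio 3", {
  # peak |differential| in signal windows vs 95th percentile of background
  for (seed in 1:10) {
    sim <- render_answer_trial(2, seed = seed)
    d <- sim$record$channels$EOG_L - sim$record$channels$EOG_R
    rate <- sim$record$rate
    sig_idx <- (73 * rate):(76 * rate)
    bg_idx <- 1:(60 * rate)
    expect_gte(max(abs(d[sig_idx])),
               3 * stats::quantile(abs(d[bg_idx]), 0.95))
  }
})

test_that("EOG deflections have opposite polarity on the two channels", {
  sim <- render_answer_trial(1, seed = 30) # single L then R
  rate <- sim$record$rate
  l_idx <- round((73.1 * rate):(73.4 * rate)) # hold of the L movement
  expect_gt(mean(sim$record$channels$EOG_L[l_idx]), 0)
  expect_lt(mean(sim$record$channels$EOG_R[l_idx]), 0)
})

test_that("chin EMG shows REM atonia relative to wake", {
  hyp <- simulate_hypnogram("normal", total_min = 60, rem_latency_min = 10,
                            confusion_prob = 0, seed = 5)
  sim <- render_record(empty_schedule(), NULL,
                       params = sim_params(rate = 50),
                       duration_s = length(hyp$truth) * 30,
                       hypnogram = hyp, seed = 6)
  chin <- sim$record$channels$EMG_chin
  rate <- sim$record$rate
  ep_rms <- vapply(seq_along(hyp$truth), function(e) {
    idx <- ((e - 1L) * 30 * rate + 1L):(e * 30 * rate)
    sqrt(mean(chin[idx]^2))
  }, numeric(1))
  expect_gte(length(ep_rms), 100L)
  expect_lt(mean(ep_rms[hyp$truth == "REM"]),
            mean(ep_rms[hyp$truth == "W"]))
})

test_that("record generation is deterministic given (config, seed)", {
  a <- render_answer_trial(3, seed = 77)
  b <- render_answer_trial(3, seed = 77)
  expect_identical(a$record$channels, b$record$channels)
  expect_identical(a$events, b$events)
})

test_that("simulated raters report truth at p_correct = 1 with HIGH confidence", {
  j <- simulate_raters(2L, p_correct = 1, seed = 8)
  expect_identical(j$count, rep(2L, 4L))
  expect_identical(j$confidence, rep("HIGH", 4L))
})

test_that("raters never false-alarm at p_false_alarm = 0", {
  j <- simulate_raters(NA, p_false_alarm = 0, seed = 9)
  expect_true(all(is.na(j$count)))
})

test_that("rater accuracy converges to p_correct", {
  set.seed(10)
  hits <- replicate(2500, {
    j <- simulate_raters(3L, n_raters = 4L, p_correct = 0.8)
    sum(j$count == 3L, na.rm = TRUE)
  })
  # 10,000 individual ratings in total
  expect_equal(sum(hits) / 10000, 0.8, tolerance = 0.0125)
})
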