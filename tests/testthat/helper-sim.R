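# Shared fixture builders. All tests use a reduced 200-Hz sampling rate for
# speed; the amplitude ratio and every other default stays at its package
# value, so detection behavior matches the 500-Hz default.

test_rate <- 200

make_schedule <- function(onsets, payload = "q", expected = NA_integer_,
                          modality = "SPOKEN", design = "USA_TLR") {
  n <- length(onsets)
  ev <- data.frame(onset_s = onsets, modality = rep(modality, n),
                   payload = rep(payload, n), intensity = rep(1L, n),
                   expected_answer = rep(as.integer(expected), n))
  structure(list(events = ev, session_design = design),
            class = "stimulus_schedule")
}

# one stimulus at 70 s with a planned LR_COUNT answer; 60-s pre-window
# baseline for the detector
render_answer_trial <- function(answer, seed, latency_s = 3,
                                ratio = 3, code_kind = "LR_COUNT") {
  sched <- make_schedule(70, expected = answer)
  plan <- data.frame(stimulus_index = 1L, action = "hit",
                     answer = as.integer(answer), code_kind = code_kind,
                     latency_s = latency_s)
  render_record(sched, plan,
                params = sim_params(rate = test_rate,
                                    signal_to_background_ratio = ratio),
                duration_s = 100, seed = seed)
}

empty_schedule <- function() {
  make_schedule(numeric(0))
}

# 4-rater judgment table from a count vector (NA = no signal seen)
judgments <- function(counts, conf = rep("HIGH", 4L)) {
  data.frame(count = as.integer(counts), confidence = conf)
}

facial_judgments <- function(muscles, counts, conf = rep("HIGH", 4L)) {
  data.frame(muscle = muscles, count = as.integer(counts), confidence = conf)
}
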