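test_that("a well-formed session validates and read/write round-trips", {
  s <- tiny_session(reps = 2)
  expect_s3_class(s, "spike_session")
  expect_equal(nrow(s$trials), 32)

  td <- withr::local_tempdir()
  tp <- file.path(td, "trials.csv")
  sp <- file.path(td, "spikes.csv")
  np <- file.path(td, "neurons.csv")
  write_session(s, tp, sp, np)
  s2 <- read_session(tp, sp, np)
  expect_equal(s2$trials$trial_id, s$trials$trial_id)
  expect_equal(s2$trials$cue_color, s$trials$cue_color)
  expect_equal(s2$trials$hold_release, s$trials$hold_release,
               tolerance = 1e-9)
  expect_equal(s2$spikes$spike_time, s$spikes$spike_time,
               tolerance = 1e-9)
  expect_equal(s2$neurons, s$neurons)
})

test_that("writing the same session twice is byte-stable", {
  s <- simulate_session(sim_config(n_neurons = c(pmPFC = 3),
                                   n_trials_per_task = 48, seed = 11))
  td <- withr::local_tempdir()
  p1 <- file.path(td, "a.csv"); p2 <- file.path(td, "b.csv")
  q1 <- file.path(td, "as.csv"); q2 <- file.path(td, "bs.csv")
  write_session(s, p1, q1)
  write_session(s, p2, q2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  expect_identical(readBin(q1, "raw", file.size(q1)),
                   readBin(q2, "raw", file.size(q2)))
})

test_that("an empty session writes and round-trips", {
  s <- spike_session(
    balanced_trials(1)[0, ],
    tibble::tibble(neuron_id = character(), trial_id = character(),
                   spike_time = double()),
    tibble::tibble(neuron_id = character(), area = character())
  )
  td <- withr::local_tempdir()
  tp <- file.path(td, "t.csv"); sp <- file.path(td, "s.csv")
  write_session(s, tp, sp)
  s2 <- read_session(tp, sp)
  expect_equal(nrow(s2$trials), 0)
  expect_equal(nrow(s2$spikes), 0)
})

test_that("validation rejects orphan references and names the rows", {
  s <- tiny_session()
  bad <- s
  bad$spikes$trial_id[3] <- "nonexistent"
  err <- expect_error(validate_session(bad), class =
                        "neurocpd_validation_error")
  expect_match(conditionMessage(err), "unknown trial_id")
  expect_match(conditionMessage(err), "rows 3")
})

test_that("validation rejects timeline violations", {
  # delay of 0.8 s (below the 1 s minimum)
  tr <- make_trial("x", delay = 0.8)
  expect_error(
    spike_session(tr, tibble::tibble(neuron_id = "u1", trial_id = "x",
                                     spike_time = 0.5)),
    "delay period"
  )
  # hold shorter than 1 s
  tr <- make_trial("x")
  tr$cue_onset <- 0.6
  tr$go_onset <- tr$cue_onset + 0.5 + 1.2
  tr$hold_release <- tr$go_onset + 0.4
  expect_error(spike_session(tr, tibble::tibble(
    neuron_id = "u1", trial_id = "x", spike_time = 0.5)), "hold period")
  # non-increasing events
  tr <- make_trial("x")
  tr$go_onset <- tr$cue_onset
  expect_error(spike_session(tr, tibble::tibble(
    neuron_id = "u1", trial_id = "x", spike_time = 0.5)),
    "strictly increasing")
  # response slower than 1 s on a correct trial
  tr <- make_trial("x", rt = 1.2)
  expect_error(spike_session(tr, tibble::tibble(
    neuron_id = "u1", trial_id = "x", spike_time = 0.5)),
    "response time")
})

test_that("validation rejects label inconsistencies on correct trials", {
  tr <- make_trial("x", tactics = "PRO", cue_color = "RED")
  expect_error(spike_session(tr, tibble::tibble(
    neuron_id = "u1", trial_id = "x", spike_time = 0.5)),
    "colour inconsistent")
  tr <- make_trial("x", tactics = "PRO", cue_position = "LEFT",
                   action = "RIGHT")
  expect_error(spike_session(tr, tibble::tibble(
    neuron_id = "u1", trial_id = "x", spike_time = 0.5)),
    "action inconsistent")
  # ...but error trials may carry any action
  tr <- make_trial("x", tactics = "PRO", cue_position = "LEFT",
                   action = "RIGHT", correct = FALSE)
  expect_silent(spike_session(tr, tibble::tibble(
    neuron_id = "u1", trial_id = "x", spike_time = 0.5)))
})

test_that("validation rejects unknown enum values and missing columns", {
  tr <- make_trial("x")
  tr$cue_color <- "PURPLE"
  expect_error(spike_session(tr, tibble::tibble(
    neuron_id = "u1", trial_id = "x", spike_time = 0.5)),
    "unknown cue_color")
  tr <- make_trial("x")
  expect_error(
    spike_session(dplyr::select(tr, -"action"), tibble::tibble(
      neuron_id = "u1", trial_id = "x", spike_time = 0.5)),
    "missing column"
  )
})

test_that("round trip is the identity on randomly generated sessions", {
  for (seed in c(3, 14, 159)) {
    s <- simulate_session(sim_config(n_neurons = c(pmPFC = 2),
                                     n_trials_per_task = 16,
                                     seed = seed))
    td <- withr::local_tempdir()
    tp <- file.path(td, "t.csv"); sp <- file.path(td, "s.csv")
    write_session(s, tp, sp)
    s2 <- read_session(tp, sp)
    expect_equal(s2$trials[, 1:7], s$trials[, 1:7])
    expect_equal(as.data.frame(s2$trials[, 8:11]),
                 as.data.frame(s$trials[, 8:11]), tolerance = 1e-8)
    expect_equal(s2$spikes$spike_time, s$spikes$spike_time,
                 tolerance = 1e-8)
  }
})

test_that("single-field mutations of a valid session are each rejected", {
  base <- tiny_session(reps = 1)
  mutate_and_check <- function(fn) {
    bad <- base
    bad <- fn(bad)
    expect_error(validate_session(bad),
                 class = "neurocpd_validation_error")
  }
  mutate_and_check(function(s) { s$trials$go_onset[1] <-
    s$trials$cue_onset[1] + 0.5 + 0.2; s })      # delay too short
  mutate_and_check(function(s) { s$trials$go_onset[1] <-
    s$trials$cue_onset[1] + 0.5 + 2.0; s })      # delay too long
  mutate_and_check(function(s) { s$trials$hold_release[1] <-
    s$trials$go_onset[1] - 0.1; s })             # events out of order
  mutate_and_check(function(s) { s$trials$tactics[1] <-
    ifelse(s$trials$tactics[1] == "PRO", "ANTI", "PRO"); s })  # colour rule
  mutate_and_check(function(s) { s$trials$action[1] <-
    ifelse(s$trials$action[1] == "LEFT", "RIGHT", "LEFT"); s })
  mutate_and_check(function(s) { s$spikes$spike_time[1] <- -0.5; s })
  mutate_and_check(function(s) { s$spikes$spike_time[1] <- 99; s })
  mutate_and_check(function(s) { s$spikes$neuron_id[1] <- "ghost"; s })
})

test_that("inclusion filter requires five correct trials in all 8 cells", {
  # exactly 5 correct trials per tactics x position cell per task
  trials <- purrr::map_dfr(
    c("TACTICS_PRECUED", "LOCATION_PRECUED"),
    function(tk) purrr::map_dfr(1:5, function(r) {
      balanced_block(tk, r, shade = if (r %% 2 == 1) 1 else -1)
    }))
  s <- spike_session(trials, phase_spikes(trials, "u1"),
                     tibble::tibble(neuron_id = "u1", area = "pmPFC"))
  expect_true(inclusion_filter(s, "u1"))
  expect_false(inclusion_filter(s, "u1", min_trials = 6))

  # drop one trial from one cell -> 4 in that cell -> fail
  drop_id <- s$trials$trial_id[s$trials$task == "TACTICS_PRECUED" &
                                 s$trials$tactics == "PRO" &
                                 s$trials$cue_position == "LEFT"][1]
  s4 <- spike_session(
    dplyr::filter(s$trials, trial_id != drop_id),
    dplyr::filter(s$spikes, trial_id != drop_id), s$neurons)
  expect_false(inclusion_filter(s4, "u1"))

  # many trials but one cell with no spikes from the neuron -> fail
  cell_ids <- s$trials$trial_id[s$trials$task == "LOCATION_PRECUED" &
                                  s$trials$tactics == "ANTI" &
                                  s$trials$cue_position == "RIGHT"]
  s_empty <- spike_session(
    s$trials, dplyr::filter(s$spikes, !trial_id %in% cell_ids),
    s$neurons)
  expect_false(inclusion_filter(s_empty, "u1"))

  expect_error(inclusion_filter(s, "ghost"), "unknown neuron_id")
})

test_that("include_neurons tabulates the rule over the population", {
  s <- tiny_session(reps = 5, neuron_ids = c("u1", "u2"))
  s$spikes <- dplyr::filter(
    s$spikes, !(neuron_id == "u2" &
                  trial_id %in% s$trials$trial_id[s$trials$tactics ==
                                                    "ANTI"]))
  inc <- include_neurons(s)
  expect_equal(inc$included, c(TRUE, FALSE))
})
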