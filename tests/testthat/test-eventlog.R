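# Event-log domain types, file I/O and decision-point construction.

test_that("trial construction validates metadata and events", {
  expect_error(crossing_trial("t", 1, "f1"), "group_size")
  expect_error(crossing_trial("t", 3, c("f1", "f2", "f3")), "each side")
  expect_error(crossing_trial("t", 3, character(0)), "each side")
  expect_error(
    crossing_trial("t", 3, "f1",
                   events = data.frame(time_s = 1, fish_id = "f1",
                                       direction = "up")),
    "direction")
  tr <- crossing_trial("t", 3, "f1")
  expect_s3_class(tr, "patch_trial")
  expect_identical(nrow(tr$events), 0L)
})

test_that("hand-written 3-fish log replays to the hand-traced configuration", {
  tr <- toy_trial()
  dp <- build_decision_points(tr)
  expect_equal(dp$n_left, c(2L, 1L, 2L, 1L, 2L))
  rp <- patchcross:::.replay_trial(tr)
  expect_identical(rp$final_n_left, 3L) # every fish ends on the left
  expect_length(rp$violations, 0)
})

test_that("decision points carry pre-event state, run lengths and memory", {
  tr <- crossing_trial("t1", 3, c("f1", "f2"),
                       events = data.frame(time_s = c(4, 5),
                                           fish_id = c("f1", "f3"),
                                           direction = c("L2R", "R2L")))
  dp <- build_decision_points(tr)
  expect_equal(dp$n_left, c(2L, 1L))
  expect_equal(dp$n_right, c(1L, 2L))
  expect_equal(dp$last_direction, c("none", "L2R"))
  expect_equal(dp$run_length, c(0L, 1L))
  expect_equal(dp$time_since_last_s, c(NA, 1.0))
  expect_equal(dp$outcome_side, c("L", "R"))
  expect_true(all(dp$informative))

  # run lengths count the maximal suffix of identical preceding directions
  tr2 <- crossing_trial("t2", 4, c("f1", "f2", "f3"),
                        events = data.frame(
                          time_s = 1:4, fish_id = c("f1", "f2", "f4", "f3"),
                          direction = c("L2R", "L2R", "R2L", "L2R")))
  expect_equal(build_decision_points(tr2)$run_length, c(0L, 1L, 2L, 1L))

  # memory window counts only events within memory_window_s of the event
  tr3 <- crossing_trial("t3", 4, c("f1", "f2", "f3"),
                        events = data.frame(
                          time_s = c(0, 1, 10), fish_id = c("f1", "f2", "f3"),
                          direction = c("L2R", "L2R", "L2R")))
  dp3 <- build_decision_points(tr3, memory_window_s = 3.5)
  expect_equal(dp3$n_recent_L2R, c(0L, 1L, 0L))
  expect_identical(nrow(build_decision_points(crossing_trial("e", 3, "f1"))), 0L)
})

test_that("an event from an empty opposite side is non-informative", {
  tr <- crossing_trial("t", 2, "f1",
                       events = data.frame(time_s = c(1, 2),
                                           fish_id = c("f1", "f2"),
                                           direction = c("L2R", "R2L")))
  dp <- build_decision_points(tr)
  expect_true(dp$informative[1])   # 1 vs 1
  expect_false(dp$informative[2])  # left empty: forced move
})

test_that("event-log files round-trip and frames convert to seconds", {
  td <- withr::local_tempdir()
  ep <- file.path(td, "events.csv"); mp <- file.path(td, "meta.csv")
  rp <- file.path(td, "roster.csv")

  # empty events + one metadata row
  writeLines("trial_id,time_s,fish_id,direction", ep)
  writeLines(c("trial_id,group_size,duration_s,fps,initial_left_ids,environment_mode",
               "T1,3,600,15,f1;f2,symmetric"), mp)
  ds <- read_event_log(ep, mp)
  expect_length(ds$trials, 1)
  expect_identical(nrow(ds$trials$T1$events), 0L)

  # frame column: frame 60 at 15 fps is 4 s
  writeLines(c("trial_id,frame,fish_id,direction", "T1,60,f1,L2R"), ep)
  ds <- read_event_log(ep, mp)
  expect_equal(ds$trials$T1$events$time_s, 4.0)

  # write/read round-trip reproduces a synthetic dataset field-for-field
  gen <- generate_dataset(synth_config(trials_per_group = c("3" = 2, "4" = 1),
                                       duration_s = 120, seed = 3))
  write_event_log(gen$dataset, ep, mp, rp)
  back <- read_event_log(ep, mp, rp)
  expect_equal(length(back$trials), length(gen$dataset$trials))
  for (id in names(gen$dataset$trials)) {
    a <- gen$dataset$trials[[id]]; b <- back$trials[[id]]
    expect_equal(b$events, a$events)
    expect_equal(b$roster$length_mm, a$roster$length_mm)
    expect_identical(b$initial_left_ids, a$initial_left_ids)
    expect_identical(b$group_size, a$group_size)
  }
})

test_that("format errors name the missing column", {
  td <- withr::local_tempdir()
  ep <- file.path(td, "events.csv"); mp <- file.path(td, "meta.csv")
  writeLines(c("trial_id,fish_id,direction", "T1,f1,L2R"), ep)
  writeLines(c("trial_id,group_size,duration_s,fps,initial_left_ids,environment_mode",
               "T1,3,600,15,f1,symmetric"), mp)
  expect_error(read_event_log(ep, mp), "time_s|frame")
  writeLines(c("trial_id,time_s,fish_id,direction", "T1,1,f1,L2R"), ep)
  writeLines(c("trial_id,group_size,duration_s,fps", "T1,3,600,15"), mp)
  expect_error(read_event_log(ep, mp), "initial_left_ids")
})

test_that("replay inconsistencies are fatal on read but reported by validate", {
  # f1 starts left but its first move is R2L
  bad <- crossing_trial("t", 3, c("f1", "f2"))
  bad$events <- data.frame(time_s = 1, fish_id = "f1", direction = "R2L",
                           stringsAsFactors = FALSE)
  expect_error(build_decision_points(bad), "f1")
  rep <- validate_dataset(crossing_dataset(list(bad)))
  expect_length(rep$violations, 1)
  expect_match(rep$violations, "side mismatch")

  # non-monotone times (constructed by direct modification)
  tr <- toy_trial()
  tr$events$time_s[3] <- 0.5
  rep2 <- validate_dataset(crossing_dataset(list(tr)))
  expect_true(any(grepl("non-monotone time", rep2$violations)))

  # a consistent dataset yields an empty violation list
  rep3 <- validate_dataset(crossing_dataset(list(toy_trial())))
  expect_length(rep3$violations, 0)
  expect_equal(rep3$summary$n_events, 5L)
})

test_that("occupancy change over decision points matches per-fish crossing parity", {
  ds <- reference_dataset(n_trials = 3, n_events = 80)
  for (tr in ds$trials) {
    dp <- build_decision_points(tr)
    # final occupancy from replay
    final_nl <- patchcross:::.replay_trial(tr)$final_n_left
    # independent: initial left fish with even crossing counts stay left,
    # right-starting fish with odd counts end left
    cnt <- table(tr$events$fish_id)
    ids <- sprintf("f%d", seq_len(tr$group_size))
    n_cross <- ifelse(ids %in% names(cnt), cnt[ids], 0)
    start_left <- ids %in% tr$initial_left_ids
    expect_identical(final_nl,
                     sum((start_left & n_cross %% 2 == 0) |
                         (!start_left & n_cross %% 2 == 1)))
    # informative points are exactly those with both sides occupied
    expect_identical(dp$informative, pmin(dp$n_left, dp$n_right) >= 1L)
    expect_lte(sum(dp$informative), nrow(tr$events))
  }
})
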