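# Shared fixtures: tiny hand-built trials and mirroring utilities.

# A 3-fish trial with 5 hand-written events (f1, f2 start left; f3 right).
# Replay by hand: n_left before each event = 2, 1, 2, 1, 2 and all three
# fish end on the left (n_left = 3).
toy_trial <- function() {
  crossing_trial(
    trial_id = "toy", group_size = 3, initial_left_ids = c("f1", "f2"),
    events = data.frame(
      time_s = c(1.0, 2.0, 4.0, 9.0, 10.0),
      fish_id = c("f1", "f3", "f2", "f2", "f1"),
      direction = c("L2R", "R2L", "L2R", "R2L", "R2L")),
    duration_s = 20)
}

# Swap left and right everywhere: directions, initial assignment. Requires
# the full fish roster to complement the initial side set.
mirror_trial <- function(trial, all_ids = NULL) {
  if (is.null(all_ids))
    all_ids <- unique(c(trial$initial_left_ids, trial$events$fish_id,
                        if (!is.null(trial$roster)) trial$roster$fish_id))
  ev <- trial$events
  ev$direction <- ifelse(ev$direction == "L2R", "R2L", "L2R")
  crossing_trial(
    trial_id = trial$trial_id, group_size = trial$group_size,
    initial_left_ids = setdiff(all_ids, trial$initial_left_ids),
    events = ev, duration_s = trial$duration_s, fps = trial$fps,
    roster = trial$roster, environment_mode = trial$environment_mode)
}

mirror_dataset <- function(dataset) {
  crossing_dataset(lapply(dataset$trials, mirror_trial))
}

# A small simulated dataset used as a reference in several suites.
reference_dataset <- function(model = "D1", params = c(alpha = 4),
                              n_trials = 4, group_size = 4,
                              n_events = 150, seed = 7) {
  designs <- lapply(seq_len(n_trials), function(i)
    simulation_design(group_size, group_size %/% 2, model, params,
                      n_events = n_events, seed = seed + i,
                      trial_id = sprintf("ref%d", i)))
  simulate_experiment(designs)
}

fast_grid <- function(n = 65) integration_settings(grid_points_per_dim = n)
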