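# Event-driven stochastic simulation of crossing sequences.
#
# Each fish carries an exponential crossing hazard base_rate * weight(side,
# state); the next crossing is the winner of the race between all fish. This
# competing-hazards construction makes the probability that the next move
# originates from the left exactly Lambda_L / (Lambda_L + Lambda_R), so the
# simulator and the sequential likelihood share one definition of every
# model. Weights (including the recent-movement memory of model D2) are
# evaluated at the time of the previous event and held constant until the
# next one.

#' Describe one simulated trial
#'
#' @param group_size Number of fish `G`.
#' @param initial_left Number of fish starting on the left (1 to `G - 1`).
#' @param model,params Generating model and its parameter values.
#' @param duration_s Stop the simulation at this time (seconds). Ignored when
#'   `n_events` is given.
#' @param n_events Alternatively stop after exactly this many crossings.
#' @param base_rate Baseline crossing hazard per fish per second
#'   (default 0.08).
#' @param seed RNG seed for this trial.
#' @param trial_id Identifier of the simulated trial.
#' @param fps Frame rate recorded in the trial metadata (default 15).
#' @param memory_window_s Memory window used by model D2 (seconds).
#' @param environment_mode `"symmetric"` or `"asymmetric"` (L = refuge).
#' @param fish_selection How the crossing individual is drawn within the
#'   origin side: `"uniform"` (default; the side-level likelihood carries no
#'   identity information) or `"round_robin"` (deterministically the fish
#'   that crossed least recently, useful for leadership fixtures).
#' @param fish_weights Optional positive per-fish selection weights (named by
#'   fish id, or unnamed of length `G`), used with `"uniform"` selection to
#'   bias which fish in the origin side crosses.
#' @param include_focal See [per_fish_weight()].
#' @return A list of class `"simulation_design"`.
#' @export
simulation_design <- function(group_size, initial_left, model = "M0",
                              params = numeric(), duration_s = 600,
                              n_events = NULL, base_rate = 0.08, seed = 1L,
                              trial_id = "sim1", fps = 15,
                              memory_window_s = 3.5,
                              environment_mode = c("symmetric", "asymmetric"),
                              fish_selection = c("uniform", "round_robin"),
                              fish_weights = NULL, include_focal = FALSE) {
  environment_mode <- match.arg(environment_mode)
  fish_selection <- match.arg(fish_selection)
  group_size <- as.integer(group_size)
  initial_left <- as.integer(initial_left)
  if (group_size < 2L) stop("group_size must be >= 2", call. = FALSE)
  if (initial_left < 1L || initial_left > group_size - 1L)
    stop("initial_left must be in 1..(G-1)", call. = FALSE)
  if (!(base_rate > 0)) stop("base_rate must be positive", call. = FALSE)
  if (is.null(n_events) && !(duration_s >= 0))
    stop("duration_s must be non-negative", call. = FALSE)
  .check_param_names(model, params)
  structure(list(group_size = group_size, initial_left = initial_left,
                 model = model, params = params, duration_s = duration_s,
                 n_events = if (is.null(n_events)) NULL else as.integer(n_events),
                 base_rate = base_rate, seed = as.integer(seed),
                 trial_id = as.character(trial_id), fps = fps,
                 memory_window_s = memory_window_s,
                 environment_mode = environment_mode,
                 fish_selection = fish_selection,
                 fish_weights = fish_weights,
                 include_focal = isTRUE(include_focal)),
            class = "simulation_design")
}

#' Simulate one crossing trial
#'
#' Runs the competing-exponential-hazards race described by a
#' [simulation_design()] and returns a [crossing_trial()] with the realised
#' event sequence. Identical design and seed yield an identical trial.
#'
#' @param design A `"simulation_design"`.
#' @return A `"patch_trial"`.
#' @export
simulate_trial <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(design$seed)
  G <- design$group_size
  ids <- sprintf("f%d", seq_len(G))
  on_left <- c(rep(TRUE, design$initial_left),
               rep(FALSE, G - design$initial_left))
  names(on_left) <- ids
  theta <- as.list(design$params)
  tau <- design$memory_window_s
  lam0 <- design$base_rate
  asym <- design$environment_mode == "asymmetric"
  sel_w <- design$fish_weights
  if (!is.null(sel_w)) {
    if (is.null(names(sel_w))) names(sel_w) <- ids
    if (any(sel_w <= 0)) stop("fish_weights must be positive", call. = FALSE)
  }
  by_time <- is.null(design$n_events)
  cap <- 4096L
  ev_t <- numeric(cap); ev_fish <- character(cap); ev_dir <- character(cap)
  n_ev <- 0L
  t_now <- 0
  last_dir <- "none"
  last_cross <- stats::setNames(rep(-Inf, G), ids) # for round-robin selection
  repeat {
    if (!by_time && n_ev >= design$n_events) break
    n_l <- sum(on_left); n_r <- G - n_l
    # net recent flow within the memory window, seen from the current time
    net <- 0L
    j <- n_ev
    while (j >= 1L && t_now - ev_t[j] <= tau) {
      net <- net + if (ev_dir[j] == "L2R") 1L else -1L
      j <- j - 1L
    }
    wl <- if (n_l > 0L)
      .fish_weight(design$model, theta, "L", n_l, n_r, last_dir, net,
                   design$include_focal) else 0
    if (asym && !is.null(theta$b)) wl <- wl * theta$b
    wr <- if (n_r > 0L)
      .fish_weight(design$model, theta, "R", n_l, n_r, last_dir, net,
                   design$include_focal) else 0
    lam_l <- n_l * lam0 * wl
    lam_r <- n_r * lam0 * wr
    lam <- lam_l + lam_r
    if (lam <= 0) stop("simulation stalled: total crossing rate is zero",
                       call. = FALSE)
    t_next <- t_now + stats::rexp(1, lam)
    if (by_time && t_next > design$duration_s) break
    t_now <- t_next
    from_left <- stats::runif(1) < lam_l / lam
    pool <- ids[on_left == from_left]
    fish <- if (design$fish_selection == "round_robin") {
      pool[order(last_cross[pool], pool)][1]
    } else if (!is.null(sel_w)) {
      if (length(pool) == 1L) pool else sample(pool, 1L, prob = sel_w[pool])
    } else {
      if (length(pool) == 1L) pool else sample(pool, 1L)
    }
    n_ev <- n_ev + 1L
    if (n_ev > cap) {
      cap <- cap * 2L
      length(ev_t) <- cap; length(ev_fish) <- cap; length(ev_dir) <- cap
    }
    ev_t[n_ev] <- t_now
    ev_fish[n_ev] <- fish
    ev_dir[n_ev] <- if (from_left) "L2R" else "R2L"
    on_left[fish] <- !from_left
    last_cross[fish] <- t_now
    last_dir <- ev_dir[n_ev]
  }
  dur <- if (by_time) design$duration_s else if (n_ev) ev_t[n_ev] else 0
  crossing_trial(
    trial_id = design$trial_id, group_size = G,
    initial_left_ids = ids[seq_len(design$initial_left)],
    events = data.frame(time_s = ev_t[seq_len(n_ev)],
                        fish_id = ev_fish[seq_len(n_ev)],
                        direction = ev_dir[seq_len(n_ev)],
                        stringsAsFactors = FALSE),
    duration_s = max(dur, .Machine$double.eps), fps = design$fps,
    environment_mode = design$environment_mode)
}

#' Simulate a multi-trial experiment
#'
#' Runs independent trials from a list of designs. When `master_seed` is
#' given, trial `i` is simulated with seed `master_seed + i`, so a whole
#' experiment is reproducible from one number.
#'
#' @param designs A list of [simulation_design()] objects.
#' @param master_seed Optional integer master seed overriding each design's
#'   own seed.
#' @return A `"patch_dataset"`; trial ids are made unique if designs repeat
#'   them.
#' @export
simulate_experiment <- function(designs, master_seed = NULL) {
  if (inherits(designs, "simulation_design")) designs <- list(designs)
  if (!length(designs)) stop("need at least one design", call. = FALSE)
  ids <- vapply(designs, `[[`, character(1), "trial_id")
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  trials <- lapply(seq_along(designs), function(i) {
    d <- designs[[i]]
    d$trial_id <- ids[i]
    if (!is.null(master_seed)) d$seed <- as.integer(master_seed) + i
    simulate_trial(d)
  })
  crossing_dataset(trials)
}
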