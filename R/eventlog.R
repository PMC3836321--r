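# Domain objects: trials, crossing events, datasets, decision points.
#
# A "crossing" is one fish moving completely over the arena's centre line.
# Sides are labelled L and R; in the asymmetric (refuge/open-water)
# configuration L denotes the refuge by convention.

.DIRECTIONS <- c("L2R", "R2L")

#' Construct a crossing trial
#'
#' A trial bundles the metadata of one experimental run (group size, duration,
#' frame rate, which fish started on the left, arena configuration) with its
#' ordered crossing events and an optional fish roster carrying body lengths.
#'
#' Fish not listed in `initial_left_ids` are taken to start on the right side.
#' Events must replay consistently: a fish can only cross from the side it is
#' currently on, so its successive crossing directions alternate.
#'
#' @param trial_id Trial identifier (coerced to character).
#' @param group_size Number of fish `G` in the trial (integer, 2--12).
#' @param initial_left_ids Character vector of fish ids that start on the left
#'   side; at least one fish must start on each side.
#' @param events Data frame with columns `time_s`, `fish_id`, `direction`
#'   (values `"L2R"`/`"R2L"`), ordered by time (ties keep row order). May have
#'   zero rows.
#' @param duration_s Trial duration in seconds (default 600, i.e. 10 min).
#' @param fps Recording frame rate in frames per second (default 15).
#' @param roster Optional data frame with columns `fish_id` and `length_mm`
#'   (body length, snout to base of tail; `NA` allowed).
#' @param environment_mode `"symmetric"` (two equivalent patches) or
#'   `"asymmetric"` (refuge vs open water; L = refuge).
#' @return An object of class `"patch_trial"`.
#' @seealso [crossing_dataset()], [build_decision_points()]
#' @export
crossing_trial <- function(trial_id, group_size, initial_left_ids,
                           events = NULL, duration_s = 600, fps = 15,
                           roster = NULL,
                           environment_mode = c("symmetric", "asymmetric")) {
  environment_mode <- match.arg(environment_mode)
  trial_id <- as.character(trial_id)
  group_size <- as.integer(group_size)
  if (is.na(group_size) || group_size < 2L || group_size > 12L)
    stop("group_size must be an integer in 2..12", call. = FALSE)
  if (!(duration_s > 0)) stop("duration_s must be positive", call. = FALSE)
  if (!(fps > 0)) stop("fps must be positive", call. = FALSE)
  initial_left_ids <- unique(as.character(initial_left_ids))
  n_left0 <- length(initial_left_ids)
  if (n_left0 < 1L || n_left0 > group_size - 1L)
    stop("need at least one fish initially on each side (1 <= |initial_left_ids| <= G-1)",
         call. = FALSE)
  if (is.null(events)) {
    events <- data.frame(time_s = numeric(0), fish_id = character(0),
                         direction = character(0), stringsAsFactors = FALSE)
  }
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  req <- c("time_s", "fish_id", "direction")
  miss <- setdiff(req, names(events))
  if (length(miss))
    stop("events is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  events <- events[, req, drop = FALSE]
  events$time_s <- as.numeric(events$time_s)
  events$fish_id <- as.character(events$fish_id)
  events$direction <- as.character(events$direction)
  if (nrow(events)) {
    if (any(is.na(events$time_s)) || any(events$time_s < 0))
      stop("event times must be non-negative", call. = FALSE)
    if (!all(events$direction %in% .DIRECTIONS))
      stop("direction must be one of ", paste(.DIRECTIONS, collapse = ", "),
           call. = FALSE)
    # stable sort: ties at the same time keep input record order
    events <- events[order(events$time_s), , drop = FALSE]
    rownames(events) <- NULL
  }
  if (!is.null(roster)) {
    roster <- as.data.frame(roster, stringsAsFactors = FALSE)
    if (!all(c("fish_id", "length_mm") %in% names(roster)))
      stop("roster needs columns fish_id and length_mm", call. = FALSE)
    roster <- roster[, c("fish_id", "length_mm"), drop = FALSE]
    roster$fish_id <- as.character(roster$fish_id)
    roster$length_mm <- as.numeric(roster$length_mm)
    if (any(!is.na(roster$length_mm) & roster$length_mm <= 0))
      stop("length_mm must be positive when present", call. = FALSE)
  }
  structure(
    list(trial_id = trial_id, group_size = group_size,
         duration_s = as.numeric(duration_s), fps = as.numeric(fps),
         initial_left_ids = initial_left_ids,
         environment_mode = environment_mode,
         events = events, roster = roster),
    class = "patch_trial")
}

#' @export
print.patch_trial <- function(x, ...) {
  cat(sprintf("<patch_trial %s> G=%d, %d events, %.0f s, %s arena\n",
              x$trial_id, x$group_size, nrow(x$events), x$duration_s,
              x$environment_mode))
  invisible(x)
}

#' Bundle trials into a dataset
#'
#' @param trials A list of [crossing_trial()] objects (a single trial is
#'   accepted and wrapped).
#' @return An object of class `"patch_dataset"` with uniquely identified
#'   trials.
#' @export
crossing_dataset <- function(trials) {
  if (inherits(trials, "patch_trial")) trials <- list(trials)
  if (!length(trials)) {
    return(structure(list(trials = list()), class = "patch_dataset"))
  }
  ok <- vapply(trials, inherits, logical(1), what = "patch_trial")
  if (!all(ok)) stop("all elements must be patch_trial objects", call. = FALSE)
  ids <- vapply(trials, `[[`, character(1), "trial_id")
  if (anyDuplicated(ids))
    stop("trial ids must be unique: ", paste(ids[duplicated(ids)], collapse = ", "),
         call. = FALSE)
  names(trials) <- ids
  structure(list(trials = trials), class = "patch_dataset")
}

#' @export
print.patch_dataset <- function(x, ...) {
  n_ev <- sum(vapply(x$trials, function(tr) nrow(tr$events), integer(1)))
  cat(sprintf("<patch_dataset> %d trial(s), %d crossing events\n",
              length(x$trials), n_ev))
  invisible(x)
}

.as_dataset <- function(x) {
  if (inherits(x, "patch_dataset")) return(x)
  if (inherits(x, "patch_trial")) return(crossing_dataset(list(x)))
  stop("expected a patch_dataset or patch_trial", call. = FALSE)
}

# Replay a trial's events against the initial side assignment. Returns, per
# event, the side occupancy immediately BEFORE the event, or stops/records a
# violation when a fish crosses from a side it is not on.
.replay_trial <- function(trial, on_error = c("stop", "collect")) {
  on_error <- match.arg(on_error)
  ev <- trial$events
  n <- nrow(ev)
  G <- trial$group_size
  side <- structure(rep("R", 0), names = character(0)) # lazily discovered
  is_left <- function(id) {
    if (!is.na(s <- side[id])) return(s == "L")
    id %in% trial$initial_left_ids
  }
  n_left <- length(trial$initial_left_ids)
  out_nl <- integer(n)
  violations <- character(0)
  viol_idx <- integer(0)
  for (i in seq_len(n)) {
    id <- ev$fish_id[i]
    from_left <- ev$direction[i] == "L2R"
    cur_left <- is_left(id)
    if (cur_left != from_left) {
      msg <- sprintf("trial %s event %d: fish %s crossed %s but is on the %s side",
                     trial$trial_id, i, id, ev$direction[i],
                     if (cur_left) "left" else "right")
      if (on_error == "stop") stop(msg, call. = FALSE)
      violations <- c(violations, msg)
      viol_idx <- c(viol_idx, i)
      # force consistency so the replay can continue
      cur_left <- from_left
      n_left <- n_left + if (cur_left) 1L else -1L
    }
    out_nl[i] <- n_left
    n_left <- n_left + if (from_left) -1L else 1L
    side[id] <- if (from_left) "R" else "L"
    if (n_left < 0L || n_left > G) {
      msg <- sprintf("trial %s event %d: occupancy left bounds [0, G]",
                     trial$trial_id, i)
      if (on_error == "stop") stop(msg, call. = FALSE)
      violations <- c(violations, msg)
      viol_idx <- c(viol_idx, i)
      n_left <- min(max(n_left, 0L), G)
    }
  }
  list(n_left_before = out_nl, final_n_left = n_left,
       violations = violations, violation_idx = viol_idx)
}

#' Convert a trial's event stream into decision points
#'
#' Each crossing event is turned into one decision point describing the state
#' of the arena immediately before the event -- how many fish were on each
#' side, the direction of the most recent crossing, the length of the run of
#' identical preceding directions, the time since the last crossing and the
#' tally of recent crossings within a memory window -- together with the
#' observed outcome (the side the move originated from). A decision point is
#' *informative* only when both sides are occupied: when one side is empty the
#' origin of the next move is forced and carries no evidence about social
#' response, so such points are excluded from all likelihoods.
#'
#' @param trial A [crossing_trial()] object.
#' @param memory_window_s Width of the recent-movement memory window in
#'   seconds (default 3.5). Crossings strictly earlier than the event and no
#'   older than this window are counted in `n_recent_L2R` / `n_recent_R2L`.
#' @return A data frame with one row per event: `event_idx`, `time_s`,
#'   `fish_id`, `direction`, `n_left`, `n_right`, `last_direction`
#'   (`"none"` before the first event), `run_length`, `time_since_last_s`
#'   (`NA` for the first event), `n_recent_L2R`, `n_recent_R2L`,
#'   `outcome_side` (`"L"` or `"R"`) and `informative`.
#' @export
build_decision_points <- function(trial, memory_window_s = 3.5) {
  stopifnot(inherits(trial, "patch_trial"), memory_window_s >= 0)
  ev <- trial$events
  n <- nrow(ev)
  G <- trial$group_size
  empty <- data.frame(
    event_idx = integer(0), time_s = numeric(0), fish_id = character(0),
    direction = character(0), n_left = integer(0), n_right = integer(0),
    last_direction = character(0), run_length = integer(0),
    time_since_last_s = numeric(0), n_recent_L2R = integer(0),
    n_recent_R2L = integer(0), outcome_side = character(0),
    informative = logical(0), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  rep_out <- .replay_trial(trial, on_error = "stop")
  n_left <- rep_out$n_left_before
  n_right <- G - n_left
  last_dir <- c("none", ev$direction[-n])
  run_length <- integer(n)
  for (i in seq_len(n)) {
    if (i == 1L) run_length[i] <- 0L
    else if (ev$direction[i - 1L] == last_dir[i] && i >= 2L) {
      # count maximal suffix of identical preceding directions
      j <- i - 1L
      while (j >= 1L && ev$direction[j] == last_dir[i]) j <- j - 1L
      run_length[i] <- (i - 1L) - j
    }
  }
  time_since <- c(NA_real_, diff(ev$time_s))
  n_l2r <- integer(n); n_r2l <- integer(n)
  for (i in seq_len(n)) {
    if (i == 1L) next
    j <- i - 1L
    while (j >= 1L && ev$time_s[i] - ev$time_s[j] <= memory_window_s) {
      if (ev$direction[j] == "L2R") n_l2r[i] <- n_l2r[i] + 1L
      else n_r2l[i] <- n_r2l[i] + 1L
      j <- j - 1L
    }
  }
  outcome <- ifelse(ev$direction == "L2R", "L", "R")
  data.frame(
    event_idx = seq_len(n), time_s = ev$time_s, fish_id = ev$fish_id,
    direction = ev$direction, n_left = n_left, n_right = n_right,
    last_direction = last_dir, run_length = run_length,
    time_since_last_s = time_since, n_recent_L2R = n_l2r,
    n_recent_R2L = n_r2l, outcome_side = outcome,
    informative = n_left >= 1L & n_right >= 1L,
    stringsAsFactors = FALSE)
}

# Aggregate the informative decision points of a dataset into unique states
# with counts. The sequential likelihood of every supported model depends on a
# decision point only through (n_left, n_right, last_direction,
# net recent flow, outcome, arena mode), so collapsing repeated states makes
# likelihood surfaces cheap to evaluate on dense parameter grids.
decision_state_table <- function(dataset, memory_window_s = 3.5) {
  dataset <- .as_dataset(dataset)
  rows <- lapply(dataset$trials, function(tr) {
    dp <- build_decision_points(tr, memory_window_s)
    dp <- dp[dp$informative, , drop = FALSE]
    if (!nrow(dp)) return(NULL)
    data.frame(n_left = dp$n_left, n_right = dp$n_right,
               last_direction = dp$last_direction,
               net_recent = dp$n_recent_L2R - dp$n_recent_R2L,
               outcome_side = dp$outcome_side,
               asymmetric = tr$environment_mode == "asymmetric",
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || !nrow(rows)) {
    return(data.frame(n_left = integer(0), n_right = integer(0),
                      last_direction = character(0), net_recent = integer(0),
                      outcome_side = character(0), asymmetric = logical(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  key <- paste(rows$n_left, rows$n_right, rows$last_direction,
               rows$net_recent, rows$outcome_side, rows$asymmetric, sep = "|")
  first <- !duplicated(key)
  out <- rows[first, , drop = FALSE]
  out$count <- as.integer(table(key)[key[first]])
  rownames(out) <- NULL
  out
}

#' Read an experiment from delimited text files
#'
#' Reads the three-file event-log format: an events CSV
#' (`trial_id,time_s|frame,fish_id,direction`), a trial metadata CSV
#' (`trial_id,group_size,duration_s,fps,initial_left_ids,environment_mode`
#' with `initial_left_ids` as a `;`-separated list) and an optional roster CSV
#' (`trial_id,fish_id,length_mm`). When the events file carries a `frame`
#' column instead of `time_s`, times are converted with
#' `time_s = frame / fps`.
#'
#' @param events_path,metadata_path,roster_path File paths; `roster_path` may
#'   be `NULL`.
#' @return A `"patch_dataset"`.
#' @export
read_event_log <- function(events_path, metadata_path, roster_path = NULL) {
  for (p in c(events_path, metadata_path, roster_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  ev <- utils::read.csv(events_path, stringsAsFactors = FALSE)
  meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  need_meta <- c("trial_id", "group_size", "duration_s", "fps",
                 "initial_left_ids", "environment_mode")
  miss <- setdiff(need_meta, names(meta))
  if (length(miss))
    stop("metadata file is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  has_time <- "time_s" %in% names(ev)
  has_frame <- "frame" %in% names(ev)
  need_ev <- c("trial_id", "fish_id", "direction")
  miss <- setdiff(need_ev, names(ev))
  if (length(miss) || !(has_time || has_frame))
    stop("events file is missing column(s): ",
         paste(c(miss, if (!(has_time || has_frame)) "time_s|frame"),
               collapse = ", "), call. = FALSE)
  roster <- NULL
  if (!is.null(roster_path)) {
    roster <- utils::read.csv(roster_path, stringsAsFactors = FALSE)
    miss <- setdiff(c("trial_id", "fish_id", "length_mm"), names(roster))
    if (length(miss))
      stop("roster file is missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  meta$trial_id <- as.character(meta$trial_id)
  ev$trial_id <- as.character(ev$trial_id)
  trials <- lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    tev <- ev[ev$trial_id == m$trial_id, , drop = FALSE]
    time_s <- if (has_time) as.numeric(tev$time_s)
              else as.numeric(tev$frame) / m$fps
    tro <- NULL
    if (!is.null(roster)) {
      tro <- roster[as.character(roster$trial_id) == m$trial_id,
                    c("fish_id", "length_mm"), drop = FALSE]
      if (!nrow(tro)) tro <- NULL
    }
    left_ids <- strsplit(as.character(m$initial_left_ids), ";", fixed = TRUE)[[1]]
    left_ids <- trimws(left_ids)
    left_ids <- left_ids[nzchar(left_ids)]
    tr <- crossing_trial(
      trial_id = m$trial_id, group_size = m$group_size,
      initial_left_ids = left_ids,
      events = data.frame(time_s = time_s, fish_id = tev$fish_id,
                          direction = tev$direction, stringsAsFactors = FALSE),
      duration_s = m$duration_s, fps = m$fps, roster = tro,
      environment_mode = m$environment_mode)
    .replay_trial(tr, on_error = "stop") # consistency check at read time
    tr
  })
  unknown <- setdiff(unique(ev$trial_id), meta$trial_id)
  if (length(unknown))
    stop("events reference trial ids absent from metadata: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  crossing_dataset(trials)
}

#' Write an experiment to delimited text files
#'
#' Inverse of [read_event_log()]: writes events, metadata and (when any trial
#' carries a roster) roster CSVs. Times are written in seconds.
#'
#' @param dataset A `"patch_dataset"`.
#' @param events_path,metadata_path Output CSV paths.
#' @param roster_path Optional roster CSV path; required if rosters exist and
#'   should be preserved.
#' @return Invisibly, the dataset.
#' @export
write_event_log <- function(dataset, events_path, metadata_path,
                            roster_path = NULL) {
  dataset <- .as_dataset(dataset)
  evs <- lapply(dataset$trials, function(tr) {
    if (!nrow(tr$events)) return(NULL)
    cbind(data.frame(trial_id = tr$trial_id, stringsAsFactors = FALSE),
          tr$events)
  })
  evs <- do.call(rbind, evs)
  if (is.null(evs))
    evs <- data.frame(trial_id = character(0), time_s = numeric(0),
                      fish_id = character(0), direction = character(0))
  meta <- do.call(rbind, lapply(dataset$trials, function(tr) {
    data.frame(trial_id = tr$trial_id, group_size = tr$group_size,
               duration_s = tr$duration_s, fps = tr$fps,
               initial_left_ids = paste(tr$initial_left_ids, collapse = ";"),
               environment_mode = tr$environment_mode,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(evs, events_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(meta, metadata_path, row.names = FALSE, quote = FALSE)
  if (!is.null(roster_path)) {
    ros <- do.call(rbind, lapply(dataset$trials, function(tr) {
      if (is.null(tr$roster)) return(NULL)
      cbind(data.frame(trial_id = tr$trial_id, stringsAsFactors = FALSE),
            tr$roster)
    }))
    if (is.null(ros))
      ros <- data.frame(trial_id = character(0), fish_id = character(0),
                        length_mm = numeric(0))
    utils::write.csv(ros, roster_path, row.names = FALSE, quote = FALSE)
  }
  invisible(dataset)
}

#' Validate a dataset
#'
#' Report-only check of dataset consistency: per-trial event counts,
#' replay violations (a fish crossing from a side it is not on, including a
#' fish listed as starting left whose first move is `R2L`) and non-monotone
#' event times. The dataset itself is never modified.
#'
#' @param dataset A `"patch_dataset"` (or single trial).
#' @return A list with `summary` (data frame: trial_id, group_size, n_events,
#'   n_informative, n_violations) and `violations` (character vector of
#'   messages, empty when the dataset is consistent).
#' @export
validate_dataset <- function(dataset) {
  dataset <- .as_dataset(dataset)
  all_viol <- character(0)
  rows <- lapply(dataset$trials, function(tr) {
    viol <- character(0)
    if (nrow(tr$events) && is.unsorted(tr$events$time_s))
      viol <- c(viol, sprintf("trial %s: non-monotone time", tr$trial_id))
    rp <- .replay_trial(tr, on_error = "collect")
    viol <- c(viol, sub("crossed (L2R|R2L) but is on the (left|right) side",
                        "side mismatch (\\1 from \\2)", rp$violations))
    n_inf <- if (length(rp$violations)) NA_integer_ else
      sum(build_decision_points(tr)$informative)
    all_viol <<- c(all_viol, viol)
    data.frame(trial_id = tr$trial_id, group_size = tr$group_size,
               n_events = nrow(tr$events), n_informative = n_inf,
               n_violations = length(viol), stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  if (is.null(summary))
    summary <- data.frame(trial_id = character(0), group_size = integer(0),
                          n_events = integer(0), n_informative = integer(0),
                          n_violations = integer(0))
  rownames(summary) <- NULL
  list(summary = summary, violations = all_viol)
}
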