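# Large-scale descriptive statistics: occupancy, crossing groups and pools,
# direction-versus-interval structure, coral-association sign tests and
# leadership scores.

#' Time-weighted side-occupancy distribution
#'
#' Proportion of trial time spent with each possible number of fish on the
#' left side. Every inter-event interval (plus the head segment before the
#' first crossing and the tail to the end of the trial) contributes its
#' duration to the prevailing occupancy.
#'
#' @param trial A [crossing_trial()].
#' @return A named numeric vector over `0..G` summing to 1.
#' @export
occupancy_distribution <- function(trial) {
  stopifnot(inherits(trial, "patch_trial"))
  if (!(trial$duration_s > 0)) stop("duration_s must be positive", call. = FALSE)
  G <- trial$group_size
  ev <- trial$events
  dur <- max(trial$duration_s, if (nrow(ev)) max(ev$time_s) else 0)
  time_at <- numeric(G + 1L) # index k+1 = time with k fish on the left
  n_left <- length(trial$initial_left_ids)
  t_prev <- 0
  if (nrow(ev)) {
    nl_before <- .replay_trial(trial, on_error = "stop")$n_left_before
    for (i in seq_len(nrow(ev))) {
      time_at[nl_before[i] + 1L] <- time_at[nl_before[i] + 1L] +
        (ev$time_s[i] - t_prev)
      t_prev <- ev$time_s[i]
      n_left <- nl_before[i] + if (ev$direction[i] == "L2R") -1L else 1L
    }
  }
  time_at[n_left + 1L] <- time_at[n_left + 1L] + (dur - t_prev)
  stats::setNames(time_at / dur, as.character(0:G))
}

#' Extract crossing groups
#'
#' A crossing group is a maximal run of consecutive same-direction crossings
#' within a trial; the time gaps between its members are unrestricted
#' (successive crossings in the same direction belong to one group no matter
#' how far apart they are), and a direction change always starts a new
#' group. The group's crossing pool is the number of fish on the origin side
#' immediately before the group's first crossing.
#'
#' @param trial A [crossing_trial()].
#' @return A data frame with one row per group: `group_idx`, `direction`,
#'   `size`, `pool`, `start_time_s`, `end_time_s`, and a list column
#'   `members` holding the fish ids in crossing order. Zero rows for an
#'   eventless trial.
#' @export
crossing_groups <- function(trial) {
  stopifnot(inherits(trial, "patch_trial"))
  ev <- trial$events
  empty <- data.frame(group_idx = integer(0), direction = character(0),
                      size = integer(0), pool = integer(0),
                      start_time_s = numeric(0), end_time_s = numeric(0),
                      stringsAsFactors = FALSE)
  if (!nrow(ev)) { empty$members <- list(); return(empty) }
  nl_before <- .replay_trial(trial, on_error = "stop")$n_left_before
  r <- rle(ev$direction)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- data.frame(
    group_idx = seq_along(r$lengths),
    direction = r$values,
    size = r$lengths,
    pool = ifelse(r$values == "L2R", nl_before[starts],
                  trial$group_size - nl_before[starts]),
    start_time_s = ev$time_s[starts],
    end_time_s = ev$time_s[ends],
    stringsAsFactors = FALSE)
  out$members <- lapply(seq_along(starts),
                        function(i) ev$fish_id[starts[i]:ends[i]])
  out
}

#' Crossing pool / group size frequency matrix
#'
#' For every crossing-pool size `m`, the conditional frequency with which a
#' crossing group of size `n` left that pool: `P(group size = n | pool = m)`.
#'
#' @param dataset A `"patch_dataset"` (or single trial).
#' @return A matrix with rows `pool = 1..G_max` and columns
#'   `size = 1..G_max`; each observed row sums to 1, rows for pool sizes
#'   never observed are `NA`.
#' @export
pool_group_matrix <- function(dataset) {
  dataset <- .as_dataset(dataset)
  groups <- do.call(rbind, lapply(dataset$trials, function(tr) {
    g <- crossing_groups(tr)
    if (!nrow(g)) NULL else g[, c("size", "pool")]
  }))
  if (is.null(groups) || !nrow(groups))
    stop("dataset contains no crossing groups", call. = FALSE)
  g_max <- max(vapply(dataset$trials, `[[`, integer(1), "group_size"))
  counts <- matrix(0, nrow = g_max, ncol = g_max,
                   dimnames = list(pool = 1:g_max, size = 1:g_max))
  for (i in seq_len(nrow(groups)))
    counts[groups$pool[i], groups$size[i]] <- counts[groups$pool[i], groups$size[i]] + 1
  rs <- rowSums(counts)
  out <- counts / rs
  out[rs == 0, ] <- NA_real_
  out
}

#' Direction of successive crossings versus the interval between them
#'
#' Classifies each pair of consecutive crossings within a trial as same- or
#' opposite-direction and bins the pairs by their inter-event interval. The
#' default binning splits at the dynamic-salience threshold of 3.5 s.
#'
#' @param dataset A `"patch_dataset"` (or single trial). Pairs never span
#'   trials.
#' @param threshold_s Interval threshold used for the default two-bin split
#'   (seconds, default 3.5).
#' @param bin_edges Optional explicit interval bin edges (overrides
#'   `threshold_s`).
#' @return A list: `by_interval` (data frame: `bin`, `n_pairs`, `p_same`),
#'   `overall_p_same`, `overall_p_opposite` and `n_pairs`. Zero-row table
#'   when no trial has two events.
#' @export
direction_interval_analysis <- function(dataset, threshold_s = 3.5,
                                        bin_edges = NULL) {
  dataset <- .as_dataset(dataset)
  if (is.null(bin_edges)) bin_edges <- c(0, threshold_s, Inf)
  pairs <- do.call(rbind, lapply(dataset$trials, function(tr) {
    ev <- tr$events
    if (nrow(ev) < 2L) return(NULL)
    data.frame(dt = diff(ev$time_s),
               same = ev$direction[-1L] == ev$direction[-nrow(ev)])
  }))
  if (is.null(pairs) || !nrow(pairs)) {
    return(list(by_interval = data.frame(bin = character(0),
                                         n_pairs = integer(0),
                                         p_same = numeric(0),
                                         stringsAsFactors = FALSE),
                overall_p_same = NA_real_, overall_p_opposite = NA_real_,
                n_pairs = 0L))
  }
  bin <- cut(pairs$dt, bin_edges, include.lowest = TRUE)
  tab <- data.frame(
    bin = levels(bin),
    n_pairs = as.integer(tapply(pairs$same, bin, length, default = 0L)),
    p_same = as.numeric(tapply(pairs$same, bin, mean, default = NA_real_)),
    stringsAsFactors = FALSE)
  list(by_interval = tab,
       overall_p_same = mean(pairs$same),
       overall_p_opposite = 1 - mean(pairs$same),
       n_pairs = nrow(pairs))
}

#' One-sided exact binomial sign test
#'
#' Exact upper-tail probability `P(X >= n_success)` for
#' `X ~ Binomial(n_trials, 1/2)`: the chance, under no side/coral
#' preference, of at least the observed number of trials favouring the
#' coral.
#'
#' @param n_trials Number of trials `N`.
#' @param n_success Number of trials with more fish on the coral.
#' @return The exact one-sided p-value.
#' @export
coral_association_test <- function(n_trials, n_success) {
  n_trials <- as.integer(n_trials); n_success <- as.integer(n_success)
  if (n_trials < 0L || n_success < 0L || n_success > n_trials)
    stop("need 0 <= n_success <= n_trials", call. = FALSE)
  stats::pbinom(n_success - 1L, n_trials, 0.5, lower.tail = FALSE)
}

.cor_or_flag <- function(x, y, min_n = 3L) {
  if (length(x) < min_n)
    return(list(r = NA_real_, p = NA_real_, n = length(x),
                flag = "too few observations"))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x),
                flag = "zero variance"))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x), flag = "ok")
}

#' Leadership scores and their correlates
#'
#' Per fish (within its trial), counts solo crossings (crossing groups of
#' size 1), initiations (first mover of groups of size >= 2) and follows
#' (later members of such groups), then pools fish across trials and
#' computes Pearson correlations of solo crossings with initiations and of
#' body length with initiations (fish with missing length are skipped for
#' the latter). Two-sided p-values come from the t transform with n - 2
#' degrees of freedom.
#'
#' @param dataset A `"patch_dataset"` (or single trial).
#' @return A list: `per_fish` (data frame: `trial_id`, `fish_id`, `solo`,
#'   `initiations`, `follows`, `crossings`, `length_mm`),
#'   `solo_vs_initiation` and `length_vs_initiation` (each a list `r`, `p`,
#'   `n`, `flag`; `flag = "zero variance"` marks undefined correlations).
#' @export
leadership_scores <- function(dataset) {
  dataset <- .as_dataset(dataset)
  per_fish <- do.call(rbind, lapply(dataset$trials, function(tr) {
    ids <- unique(c(tr$initial_left_ids, tr$events$fish_id,
                    if (!is.null(tr$roster)) tr$roster$fish_id))
    g <- crossing_groups(tr)
    solo <- init <- foll <- stats::setNames(integer(length(ids)), ids)
    for (i in seq_len(nrow(g))) {
      mem <- g$members[[i]]
      if (g$size[i] == 1L) solo[mem] <- solo[mem] + 1L
      else {
        init[mem[1L]] <- init[mem[1L]] + 1L
        for (f in mem[-1L]) foll[f] <- foll[f] + 1L
      }
    }
    cross <- stats::setNames(integer(length(ids)), ids)
    if (nrow(tr$events)) {
      tb <- table(tr$events$fish_id)
      cross[names(tb)] <- as.integer(tb)
    }
    len <- rep(NA_real_, length(ids))
    if (!is.null(tr$roster))
      len <- tr$roster$length_mm[match(ids, tr$roster$fish_id)]
    data.frame(trial_id = tr$trial_id, fish_id = ids, solo = unname(solo),
               initiations = unname(init), follows = unname(foll),
               crossings = unname(cross), length_mm = len,
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_fish))
    per_fish <- data.frame(trial_id = character(0), fish_id = character(0),
                           solo = integer(0), initiations = integer(0),
                           follows = integer(0), crossings = integer(0),
                           length_mm = numeric(0))
  rownames(per_fish) <- NULL
  with_len <- per_fish[!is.na(per_fish$length_mm), , drop = FALSE]
  list(per_fish = per_fish,
       solo_vs_initiation = .cor_or_flag(per_fish$solo, per_fish$initiations),
       length_vs_initiation = .cor_or_flag(with_len$length_mm,
                                           with_len$initiations))
}
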