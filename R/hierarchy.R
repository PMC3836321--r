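# Dominance-hierarchy statistics on leader--follower relations.
#
# Within each crossing group, each fish "follows" the fish that crossed
# immediately before it. The per-trial follow matrix F counts these ordered
# pairs; the dominance digraph keeps the majority direction of each dyad.
# Hierarchy linearity is Kendall's K from the number of circular triads, with
# a Monte Carlo null obtained by redirecting every dyad's follow events with
# fair coin flips, and per-trial p-values are combined across trials with
# Fisher's omnibus chi-squared statistic.

#' Follow matrix of a trial
#'
#' `F[i, j]` counts how often fish `j` crossed immediately after fish `i`
#' within a crossing group (groups of size >= 2 only).
#'
#' @param trial A [crossing_trial()].
#' @return A square integer matrix indexed by fish id.
#' @export
follow_matrix <- function(trial) {
  stopifnot(inherits(trial, "patch_trial"))
  ids <- sort(unique(c(trial$initial_left_ids, trial$events$fish_id,
                       if (!is.null(trial$roster)) trial$roster$fish_id)))
  f <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  g <- crossing_groups(trial)
  for (i in seq_len(nrow(g))) {
    mem <- g$members[[i]]
    if (length(mem) < 2L) next
    for (k in 2:length(mem))
      f[mem[k - 1L], mem[k]] <- f[mem[k - 1L], mem[k]] + 1L
  }
  f
}

# Circular-triad count with tie handling. Dyads with F[i,j] == F[j,i]
# (including 0-0) are undecided and every triad containing one is skipped;
# the maximum possible count is scaled down by the fraction of decided
# triads.
.triad_stats <- function(f, triads) {
  wins <- f > t(f)
  decided <- wins | t(wins)
  d <- 0L; n_dec <- 0L
  for (k in seq_len(ncol(triads))) {
    i <- triads[1L, k]; j <- triads[2L, k]; l <- triads[3L, k]
    if (!(decided[i, j] && decided[j, l] && decided[i, l])) next
    n_dec <- n_dec + 1L
    out_deg <- c(wins[i, j] + wins[i, l], wins[j, i] + wins[j, l],
                 wins[l, i] + wins[l, j])
    if (all(out_deg == 1L)) d <- d + 1L # circular: no clear top of the triad
  }
  list(d = d, n_decided = n_dec)
}

#' Kendall linearity of a follow matrix
#'
#' Computes the circular-triad count `d` and Kendall's linearity coefficient
#' `K = 1 - d / d_max`, with `d_max = (n^3 - n) / 24` for odd `n` and
#' `(n^3 - 4n) / 24` for even `n`. Tied dyads (equal counts in both
#' directions, including no interaction) are excluded together with any
#' triad containing one, and `d_max` is scaled by the fraction of decided
#' triads; `K` is `NA` when no triad is decided.
#'
#' @param f A square follow-count matrix.
#' @return A list: `K`, `d`, `d_max` (effective maximum), `n_decided_triads`,
#'   `n_triads`, `n` (matrix dimension).
#' @export
kendall_linearity <- function(f) {
  n <- nrow(f)
  if (is.null(n) || n != ncol(f)) stop("f must be square", call. = FALSE)
  if (n < 3L)
    return(list(K = NA_real_, d = NA_integer_, d_max = NA_real_,
                n_decided_triads = 0L, n_triads = 0L, n = n))
  triads <- utils::combn(n, 3L)
  st <- .triad_stats(f, triads)
  d_max_full <- if (n %% 2L == 1L) (n^3 - n) / 24 else (n^3 - 4 * n) / 24
  d_max <- d_max_full * st$n_decided / ncol(triads)
  K <- if (d_max > 0) max(0, min(1, 1 - st$d / d_max)) else NA_real_
  list(K = K, d = st$d, d_max = d_max, n_decided_triads = st$n_decided,
       n_triads = ncol(triads), n = n)
}

#' Fisher omnibus combination of p-values
#'
#' Combines independent p-values with `chi2 = -2 * sum(log(p))` on
#' `2 * length(p)` degrees of freedom.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return A list: `chi2`, `df`, `p_value`.
#' @export
fisher_omnibus <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) stop("no p-values to combine", call. = FALSE)
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]", call. = FALSE)
  chi2 <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Monte Carlo linearity test of one follow matrix
#'
#' Tests whether a follow matrix is more linear (fewer circular triads) than
#' expected when every dyad's follow events are redirected by independent
#' fair coin flips. Because Kendall's `K` is discrete, the randomised Monte
#' Carlo p-value is returned:
#' `p = (#{K_null > K_obs} + U * (1 + #{K_null == K_obs})) / (1 + n_def)`,
#' with `U ~ Uniform(0, 1)` and `n_def` the number of null draws whose `K`
#' is defined. Under the coin-flip null this p-value is exactly uniform,
#' which keeps Fisher's combination across trials calibrated.
#'
#' @param f A square follow-count matrix (see [follow_matrix()]).
#' @param n_mc Number of null redirections (default 10000).
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return A list: `K`, `d`, `d_max`, `p_mc` (`NA` when `K` is undefined),
#'   `n_defined`.
#' @export
kendall_mc_test <- function(f, n_mc = 10000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_mc <- as.integer(n_mc)
  n <- nrow(f)
  obs <- kendall_linearity(f)
  if (is.na(obs$K))
    return(list(K = NA_real_, d = obs$d, d_max = obs$d_max, p_mc = NA_real_,
                n_defined = 0L))
  triads <- utils::combn(n, 3L)
  d_max_full <- if (n %% 2L == 1L) (n^3 - n) / 24 else (n^3 - 4 * n) / 24
  up <- which(upper.tri(f))
  tot <- f[up] + t(f)[up]
  n_gt <- 0L; n_eq <- 0L; n_def <- 0L
  for (r in seq_len(n_mc)) {
    fw <- stats::rbinom(length(tot), tot, 0.5)
    fn <- matrix(0L, n, n)
    fn[up] <- fw
    fn <- t(fn); fn[up] <- tot - fw; fn <- t(fn)
    st <- .triad_stats(fn, triads)
    d_max_n <- d_max_full * st$n_decided / ncol(triads)
    k_null <- if (d_max_n > 0) max(0, min(1, 1 - st$d / d_max_n)) else NA
    if (is.na(k_null)) next
    n_def <- n_def + 1L
    if (k_null > obs$K) n_gt <- n_gt + 1L
    else if (k_null == obs$K) n_eq <- n_eq + 1L
  }
  list(K = obs$K, d = obs$d, d_max = obs$d_max,
       p_mc = (n_gt + stats::runif(1) * (1 + n_eq)) / (1 + n_def),
       n_defined = n_def)
}

#' Hierarchy linearity test across trials
#'
#' For every trial with at least three fish and at least one crossing group
#' of size >= 2, builds the follow matrix, computes Kendall's linearity `K`,
#' and derives a Monte Carlo p-value by redirecting each dyad's follow events
#' with independent fair coin flips. Because `K` is a discrete statistic, the
#' randomised Monte Carlo p-value is used:
#' `p = (#{K_null > K_obs} + U * (1 + #{K_null == K_obs})) / (1 + n_def)`
#' with `U ~ Uniform(0, 1)` and `n_def` the number of null draws with a
#' defined `K`. This p-value is exactly uniform under the null, which keeps
#' the downstream Fisher combination calibrated; an unrandomised tail count
#' would be conservative. Trials whose `K` is undefined (no decided triad)
#' are excluded. The per-trial p-values are combined with [fisher_omnibus()]
#' on `2 x (number of combined trials)` degrees of freedom.
#'
#' @param dataset A `"patch_dataset"` (or single trial).
#' @param n_mc Number of Monte Carlo null matrices per trial (default 10000).
#' @param seed RNG seed.
#' @return A list: `per_trial` (data frame: `trial_id`, `n_fish`,
#'   `n_follow_events`, `d`, `d_max`, `K`, `p_mc`, `included`), `n_combined`,
#'   `chi2`, `df`, `p_value`, and `excluded` (ids of skipped trials).
#' @export
hierarchy_test <- function(dataset, n_mc = 10000L, seed = 1L) {
  dataset <- .as_dataset(dataset)
  set.seed(seed)
  n_mc <- as.integer(n_mc)
  rows <- list(); excluded <- character(0)
  for (tr in dataset$trials) {
    f <- follow_matrix(tr)
    n <- nrow(f)
    n_follow <- sum(f)
    if (n < 3L || n_follow < 1L) {
      excluded <- c(excluded, tr$trial_id)
      rows[[length(rows) + 1L]] <- data.frame(
        trial_id = tr$trial_id, n_fish = n, n_follow_events = n_follow,
        d = NA_integer_, d_max = NA_real_, K = NA_real_, p_mc = NA_real_,
        included = FALSE, stringsAsFactors = FALSE)
      next
    }
    mc <- kendall_mc_test(f, n_mc = n_mc)
    if (is.na(mc$K)) {
      excluded <- c(excluded, tr$trial_id)
      rows[[length(rows) + 1L]] <- data.frame(
        trial_id = tr$trial_id, n_fish = n, n_follow_events = n_follow,
        d = mc$d, d_max = mc$d_max, K = NA_real_, p_mc = NA_real_,
        included = FALSE, stringsAsFactors = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      trial_id = tr$trial_id, n_fish = n, n_follow_events = n_follow,
      d = mc$d, d_max = mc$d_max, K = mc$K, p_mc = mc$p_mc,
      included = TRUE, stringsAsFactors = FALSE)
  }
  per_trial <- do.call(rbind, rows)
  if (is.null(per_trial))
    per_trial <- data.frame(trial_id = character(0), n_fish = integer(0),
                            n_follow_events = integer(0), d = integer(0),
                            d_max = numeric(0), K = numeric(0),
                            p_mc = numeric(0), included = logical(0))
  rownames(per_trial) <- NULL
  p_ok <- per_trial$p_mc[per_trial$included]
  if (length(p_ok)) {
    fo <- fisher_omnibus(p_ok)
  } else {
    fo <- list(chi2 = NA_real_, df = 0L, p_value = NA_real_)
  }
  list(per_trial = per_trial, n_combined = length(p_ok), chi2 = fo$chi2,
       df = fo$df, p_value = fo$p_value, excluded = excluded)
}
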