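# The competing social-response models.
#
# Every model assigns each fish a non-negative crossing propensity (weight)
# that depends on the current state of the arena. The side-level rate is
# Lambda_side = n_side * w_side, and the probability that the next crossing
# originates from the left is Lambda_L / (Lambda_L + Lambda_R). The sequential
# likelihood of a dataset multiplies these outcome probabilities over all
# informative decision points (both sides occupied).
#
# A fish's response is driven by Delta = n_opposite - (n_same - 1): the excess
# of conspecifics on the far side over neighbours on its own side (the focal
# fish does not count itself; set include_focal = TRUE to include it).

.S2_FLOOR <- 1e-9

.MODEL_DEFS <- list(
  M0 = list(class = "null",     params = character(0),      core = TRUE),
  S1 = list(class = "static",   params = "gamma",           core = TRUE),
  S2 = list(class = "static",   params = "beta",            core = TRUE),
  S3 = list(class = "static",   params = "g",               core = TRUE),
  S4 = list(class = "static",   params = c("a", "s"),       core = TRUE),
  D1 = list(class = "dynamic",  params = "alpha",           core = TRUE),
  D2 = list(class = "dynamic",  params = "alpha",           core = TRUE),
  C1 = list(class = "combined", params = c("gamma", "alpha"), core = FALSE)
)

# Default closed parameter supports. Multiplicative factors live on a
# symmetric dyadic range around 1; the linear slope beta is bounded so the
# response stays comparable over Delta of a few fish; the steepness s of the
# logistic (S4) model must exceed 1.
.PARAM_BOUNDS <- list(
  gamma = c(2^-6, 2^6), beta = c(-5, 5), g = c(2^-6, 2^6),
  a = c(2^-6, 2^6), s = c(1 + 2^-6, 2^6), alpha = c(2^-6, 2^6),
  b = c(2^-6, 2^6))

#' List the supported decision models
#'
#' The core set holds one null model, four static (occupancy-driven) response
#' models and two dynamic (recent-movement-driven) models:
#' \describe{
#'   \item{M0}{null: every fish equally likely to cross next.}
#'   \item{S1}{binary response: weight `gamma` towards the larger group,
#'     regardless of how much larger it is.}
#'   \item{S2}{linear response: weight `1 + beta * Delta`, floored at a tiny
#'     positive value.}
#'   \item{S3}{geometric response: weight `g^Delta`.}
#'   \item{S4}{Bayesian-decision (logistic) response:
#'     `1 / (1 + a * s^-Delta)`.}
#'   \item{D1}{follow the last mover: weight `alpha` for fish on the origin
#'     side of the most recent crossing.}
#'   \item{D2}{recent-movers memory: weight `alpha^m`, where `m` is the net
#'     number of crossings within the memory window that a move from the
#'     fish's side would continue.}
#' }
#' The extension model C1 multiplies the S1 and D1 weights (parameters
#' `gamma`, `alpha`).
#'
#' @param include_extensions Also list the combined model C1 (default FALSE).
#' @return A data frame with columns `name`, `class`, `n_params`, `params`
#'   (comma-separated) and `core`.
#' @export
list_models <- function(include_extensions = FALSE) {
  nm <- names(.MODEL_DEFS)
  out <- data.frame(
    name = nm,
    class = vapply(.MODEL_DEFS, `[[`, character(1), "class"),
    n_params = vapply(.MODEL_DEFS, function(d) length(d$params), integer(1)),
    params = vapply(.MODEL_DEFS, function(d) paste(d$params, collapse = ","),
                    character(1)),
    core = vapply(.MODEL_DEFS, `[[`, logical(1), "core"),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!include_extensions) out <- out[out$core, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Parameter names of a model
#' @param model Model name (`"M0"`, `"S1"`, ..., `"C1"`).
#' @return Character vector of parameter names (empty for `M0`).
#' @export
model_params <- function(model) {
  def <- .MODEL_DEFS[[model]]
  if (is.null(def)) stop("unknown model: ", model, call. = FALSE)
  def$params
}

# Name check only: simulation may explore parameter values outside the
# default prior support (e.g. limiting regimes), inference may not.
.check_param_names <- function(model, params) {
  need <- model_params(model)
  params <- as.list(params)
  miss <- setdiff(need, names(params))
  if (length(miss))
    stop(model, ": missing parameter(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(unlist(params[need]) > -Inf) || anyNA(unlist(params[need])))
    stop(model, ": parameters must be finite", call. = FALSE)
  params
}

.check_params <- function(model, params) {
  need <- model_params(model)
  params <- as.list(params)
  miss <- setdiff(need, names(params))
  if (length(miss))
    stop(model, ": missing parameter(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (p in need) {
    b <- .PARAM_BOUNDS[[p]]
    v <- params[[p]]
    if (any(v < b[1] - 1e-12) || any(v > b[2] + 1e-12))
      stop(sprintf("%s: parameter %s outside bounds [%g, %g]", model, p,
                   b[1], b[2]), call. = FALSE)
  }
  params
}

# Vectorised (over theta) per-fish weight for a scalar state. `theta` is a
# list of equal-length numeric vectors keyed by parameter name. `last_dir`
# is "L2R", "R2L" or "none"; `net_recent` = recent L2R count - recent R2L
# count within the memory window.
.fish_weight <- function(model, theta, side, n_left, n_right, last_dir,
                         net_recent, include_focal = FALSE) {
  n_same <- if (side == "L") n_left else n_right
  n_opp <- if (side == "L") n_right else n_left
  delta <- n_opp - n_same + (if (include_focal) 0L else 1L)
  switch(model,
    M0 = 1,
    S1 = theta$gamma ^ sign(delta),
    S2 = pmax(.S2_FLOOR, 1 + theta$beta * delta),
    S3 = theta$g ^ delta,
    S4 = 1 / (1 + theta$a * theta$s ^ (-delta)),
    D1 = if (identical(last_dir, if (side == "L") "L2R" else "R2L"))
           theta$alpha else 1,
    D2 = theta$alpha ^ (if (side == "L") net_recent else -net_recent),
    C1 = .fish_weight("S1", theta, side, n_left, n_right, last_dir,
                      net_recent, include_focal) *
         .fish_weight("D1", theta, side, n_left, n_right, last_dir,
                      net_recent, include_focal),
    stop("unknown model: ", model, call. = FALSE))
}

# Vectorised probability that the next move originates from the left.
# In the asymmetric (refuge/open) configuration the refuge side (L) weight is
# multiplied by the side-bias parameter b when supplied.
.side_prob_L <- function(model, theta, n_left, n_right, last_dir, net_recent,
                         asymmetric = FALSE, include_focal = FALSE) {
  bias <- if (asymmetric && !is.null(theta$b)) theta$b else 1
  wl <- if (n_left > 0)
    .fish_weight(model, theta, "L", n_left, n_right, last_dir, net_recent,
                 include_focal) * bias else 0
  wr <- if (n_right > 0)
    .fish_weight(model, theta, "R", n_left, n_right, last_dir, net_recent,
                 include_focal) else 0
  lam_l <- n_left * wl
  lam_r <- n_right * wr
  tot <- lam_l + lam_r
  if (any(tot <= 0))
    stop("degenerate state: total crossing rate is zero", call. = FALSE)
  lam_l / tot
}

.state_args <- function(state) {
  state <- as.list(state)
  list(n_left = as.integer(state$n_left),
       n_right = as.integer(state$n_right),
       last_dir = if (is.null(state$last_direction)) "none"
                  else as.character(state$last_direction),
       net_recent = if (is.null(state$net_recent)) {
         if (!is.null(state$n_recent_L2R))
           as.integer(state$n_recent_L2R) - as.integer(state$n_recent_R2L)
         else 0L
       } else as.integer(state$net_recent),
       asymmetric = isTRUE(state$asymmetric))
}

#' Per-fish crossing propensity under a model
#'
#' Evaluates the weight a single fish on `side` receives in a given decision
#' state. Weights are relative propensities: the null model's weight is 1 and
#' the side-level crossing rate is proportional to `n_side * weight`.
#'
#' @param model Model name (see [list_models()]).
#' @param params Named numeric vector/list of parameter values within bounds.
#' @param side `"L"` or `"R"`.
#' @param state A list (or one-row decision-point data frame) with at least
#'   `n_left` and `n_right`; optionally `last_direction`, `net_recent` (or
#'   `n_recent_L2R`/`n_recent_R2L`) and `asymmetric`.
#' @param include_focal Count the focal fish in its own side when forming the
#'   occupancy difference `Delta` (default FALSE: a fish responds to its
#'   neighbours, not itself).
#' @return A non-negative scalar weight.
#' @export
per_fish_weight <- function(model, params = numeric(), side, state,
                            include_focal = FALSE) {
  side <- match.arg(side, c("L", "R"))
  theta <- .check_params(model, params)
  st <- .state_args(state)
  w <- .fish_weight(model, theta, side, st$n_left, st$n_right, st$last_dir,
                    st$net_recent, include_focal)
  if (st$asymmetric && side == "L" && !is.null(theta$b)) w <- w * theta$b
  as.numeric(w)
}

#' Probability that the next crossing originates from the left
#'
#' `P(L) = Lambda_L / (Lambda_L + Lambda_R)` with
#' `Lambda_side = n_side * per_fish_weight(side)`. An empty side has
#' probability zero; `P(L) + P(R) = 1` always.
#'
#' @inheritParams per_fish_weight
#' @return Probability in `[0, 1]`.
#' @export
side_probability <- function(model, params = numeric(), state,
                             include_focal = FALSE) {
  theta <- .check_params(model, params)
  st <- .state_args(state)
  if (st$n_left + st$n_right < 1L)
    stop("state must contain at least one fish", call. = FALSE)
  if (st$n_left == 0L) return(0)
  if (st$n_right == 0L) return(1)
  as.numeric(.side_prob_L(model, theta, st$n_left, st$n_right, st$last_dir,
                          st$net_recent, st$asymmetric, include_focal))
}

# Log2 likelihood over an aggregated state table, vectorised over theta.
.state_loglik <- function(model, theta, states, include_focal = FALSE) {
  m <- if (length(theta)) max(lengths(theta)) else 1L
  out <- numeric(m)
  for (k in seq_len(nrow(states))) {
    pl <- .side_prob_L(model, theta, states$n_left[k], states$n_right[k],
                       states$last_direction[k], states$net_recent[k],
                       states$asymmetric[k], include_focal)
    p <- if (states$outcome_side[k] == "L") pl else 1 - pl
    out <- out + states$count[k] * log2(pmax(p, .Machine$double.xmin))
  }
  out
}

#' Sequential log-likelihood of a dataset under a model
#'
#' Sums `log P(outcome side)` over all informative decision points of the
#' dataset (both sides occupied immediately before the event). Events from a
#' configuration with an empty opposite side are forced moves and contribute
#' nothing.
#'
#' @param model Model name.
#' @param params Named parameter values.
#' @param dataset A `"patch_dataset"` (or single trial).
#' @param base Logarithm base for reporting (default 2).
#' @param memory_window_s Memory window for the recent-movement tallies used
#'   by model D2 (seconds, default 3.5).
#' @param include_focal See [per_fish_weight()].
#' @return The log-likelihood (0 for an empty or all-forced dataset).
#' @export
log_likelihood <- function(model, params = numeric(), dataset, base = 2,
                           memory_window_s = 3.5, include_focal = FALSE) {
  theta <- .check_params(model, params)
  states <- decision_state_table(dataset, memory_window_s)
  ll2 <- .state_loglik(model, theta, states, include_focal)
  ll2 * log(2) / log(base)
}
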