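# Bayesian model comparison via log2 marginal likelihoods.
#
# Evidence for a model is P(D | M) = integral over its parameter prior of the
# sequential likelihood. Grid integration (deterministic, trapezoid weights on
# the prior's natural scale) is the default; Monte Carlo prior sampling is the
# independent cross-check.

#' Default parameter priors for a model
#'
#' Multiplicative response factors (`gamma`, `g`, `alpha`, `a`, `s`, `b`) get
#' scale-free log-uniform priors over `[2^-6, 2^6]` (the logistic steepness
#' `s` over `[1 + 2^-6, 2^6]`); the linear slope `beta` gets a uniform prior
#' over `[-5, 5]`. Priors are normalised over their support.
#'
#' @param model Model name (see [list_models()]).
#' @param side_bias Add a log-uniform prior on the refuge side-bias
#'   multiplier `b` (asymmetric arenas only; default FALSE).
#' @return A data frame with columns `param`, `dist`
#'   (`"log_uniform"`/`"uniform"`), `lo`, `hi`.
#' @export
default_priors <- function(model, side_bias = FALSE) {
  pars <- model_params(model)
  if (side_bias) pars <- c(pars, "b")
  if (!length(pars)) {
    return(data.frame(param = character(0), dist = character(0),
                      lo = numeric(0), hi = numeric(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    param = pars,
    dist = ifelse(pars == "beta", "uniform", "log_uniform"),
    lo = vapply(pars, function(p) .PARAM_BOUNDS[[p]][1], numeric(1)),
    hi = vapply(pars, function(p) .PARAM_BOUNDS[[p]][2], numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Integration settings for evidence computation
#'
#' @param method `"grid"` (default; deterministic tensor-grid quadrature with
#'   trapezoid weights) or `"monte_carlo"` (mean likelihood under prior
#'   draws).
#' @param grid_points_per_dim Grid nodes per parameter dimension (>= 3,
#'   default 513).
#' @param mc_samples Number of Monte Carlo prior draws (>= 100, default
#'   20000).
#' @param rng_seed Seed used by the Monte Carlo method.
#' @return A list of class `"integration_settings"`.
#' @export
integration_settings <- function(method = c("grid", "monte_carlo"),
                                 grid_points_per_dim = 513L,
                                 mc_samples = 20000L, rng_seed = 1L) {
  method <- match.arg(method)
  grid_points_per_dim <- as.integer(grid_points_per_dim)
  mc_samples <- as.integer(mc_samples)
  if (grid_points_per_dim < 3L) stop("grid_points_per_dim must be >= 3")
  if (mc_samples < 100L) stop("mc_samples must be >= 100")
  structure(list(method = method,
                 grid_points_per_dim = grid_points_per_dim,
                 mc_samples = mc_samples, rng_seed = as.integer(rng_seed)),
            class = "integration_settings")
}

.check_prior <- function(prior) {
  stopifnot(is.data.frame(prior),
            all(c("param", "dist", "lo", "hi") %in% names(prior)))
  if (any(prior$lo >= prior$hi)) stop("prior must have lo < hi", call. = FALSE)
  if (!all(prior$dist %in% c("log_uniform", "uniform")))
    stop("prior dist must be log_uniform or uniform", call. = FALSE)
  prior
}

# Per-parameter quadrature nodes on the prior's natural scale (log theta for
# log-uniform, theta for uniform) with trapezoid prior masses summing to 1.
.prior_nodes_1d <- function(dist, lo, hi, n) {
  if (dist == "log_uniform") {
    u <- seq(log(lo), log(hi), length.out = n)
    theta <- exp(u)
  } else {
    u <- seq(lo, hi, length.out = n)
    theta <- u
  }
  h <- u[2] - u[1]
  w <- rep(h, n); w[c(1, n)] <- h / 2
  mass <- w / (u[n] - u[1]) # trapezoid weight x uniform density in u
  list(theta = theta, mass = mass)
}

# Tensor grid over all parameters: list(theta = named list of vectors,
# log2_mass = vector). Total prior mass is exactly 1.
.prior_grid <- function(prior, n_per_dim) {
  dims <- lapply(seq_len(nrow(prior)), function(i)
    .prior_nodes_1d(prior$dist[i], prior$lo[i], prior$hi[i], n_per_dim))
  idx <- do.call(expand.grid, lapply(dims, function(d) seq_along(d$theta)))
  theta <- lapply(seq_along(dims), function(i) dims[[i]]$theta[idx[[i]]])
  names(theta) <- prior$param
  log2_mass <- Reduce(`+`, lapply(seq_along(dims), function(i)
    log2(dims[[i]]$mass[idx[[i]]])))
  list(theta = theta, log2_mass = log2_mass)
}

.prior_draws <- function(prior, n) {
  theta <- lapply(seq_len(nrow(prior)), function(i) {
    if (prior$dist[i] == "log_uniform")
      exp(stats::runif(n, log(prior$lo[i]), log(prior$hi[i])))
    else stats::runif(n, prior$lo[i], prior$hi[i])
  })
  names(theta) <- prior$param
  theta
}

.logsumexp2 <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log2(sum(2^(x - m)))
}

#' Log2 marginal likelihood of a model on a dataset
#'
#' Integrates the sequential likelihood over the parameter prior to obtain
#' `log2 P(data | model)`. The grid method applies trapezoid quadrature on
#' the prior's natural scale (log-scale for log-uniform priors) and combines
#' nodes by log-sum-exp; the Monte Carlo method reports the log of the mean
#' likelihood under prior draws with a fixed seed. A model without free
#' parameters (M0) has evidence identical to its log-likelihood, and any
#' model's evidence on a dataset with no informative decision point is 0.
#'
#' @param model Model name.
#' @param dataset A `"patch_dataset"` (or single trial).
#' @param prior Prior data frame as from [default_priors()] (the default).
#' @param settings An [integration_settings()] object.
#' @param memory_window_s Memory window for model D2 (seconds).
#' @param include_focal See [per_fish_weight()].
#' @return An object of class `"model_evidence"`: a list with `model`,
#'   `log2_evidence`, `map_params` (named vector at the posterior grid mode),
#'   `posterior` (data frame of grid parameter values and normalised
#'   posterior masses), `n_informative`, `method`, `prior` and `settings`.
#' @export
log_marginal_likelihood <- function(model, dataset,
                                    prior = default_priors(model),
                                    settings = integration_settings(),
                                    memory_window_s = 3.5,
                                    include_focal = FALSE) {
  prior <- .check_prior(prior)
  need <- model_params(model)
  miss <- setdiff(need, prior$param)
  if (length(miss))
    stop("prior is missing parameter(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  states <- decision_state_table(dataset, memory_window_s)
  n_inf <- sum(states$count)
  if (!nrow(prior)) {
    ev <- .state_loglik(model, list(), states, include_focal)
    return(structure(list(model = model, log2_evidence = ev,
                          map_params = stats::setNames(numeric(0), character(0)),
                          posterior = NULL, n_informative = n_inf,
                          method = "exact", prior = prior,
                          settings = settings),
                     class = "model_evidence"))
  }
  if (settings$method == "grid") {
    grid <- .prior_grid(prior, settings$grid_points_per_dim)
    ll <- .state_loglik(model, grid$theta, states, include_focal)
    if (any(!is.finite(ll)))
      stop(sprintf("non-finite likelihood at grid point %d of model %s",
                   which(!is.finite(ll))[1], model), call. = FALSE)
    joint <- ll + grid$log2_mass
    # normalising by the summed prior mass removes trapezoid round-off and
    # makes the evidence of a zero-information dataset exactly 0
    ev <- .logsumexp2(joint) - .logsumexp2(grid$log2_mass)
    mass <- 2^(joint - ev)
    mass <- mass / sum(mass)
    post <- as.data.frame(grid$theta)
    post$mass <- mass
    map_i <- which.max(joint)
  } else {
    set.seed(settings$rng_seed)
    theta <- .prior_draws(prior, settings$mc_samples)
    ll <- .state_loglik(model, theta, states, include_focal)
    ev <- .logsumexp2(ll) - log2(settings$mc_samples)
    w <- 2^(ll - max(ll))
    mass <- w / sum(w)
    post <- as.data.frame(theta)
    post$mass <- mass
    map_i <- which.max(ll)
  }
  map <- vapply(prior$param, function(p) post[[p]][map_i], numeric(1))
  structure(list(model = model, log2_evidence = ev, map_params = map,
                 posterior = post, n_informative = n_inf,
                 method = settings$method, prior = prior,
                 settings = settings),
            class = "model_evidence")
}

#' @export
print.model_evidence <- function(x, ...) {
  cat(sprintf("<model_evidence %s> log2 evidence = %.3f (%s; %d informative decision points)\n",
              x$model, x$log2_evidence, x$method, x$n_informative))
  if (length(x$map_params))
    cat("  MAP:", paste(sprintf("%s=%.4g", names(x$map_params), x$map_params),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Compare models by marginal likelihood
#'
#' Computes the log2 evidence of each requested model on the same dataset and
#' ranks models from most to least probable. Ties preserve the registry order
#' of [list_models()].
#'
#' @param dataset A `"patch_dataset"`.
#' @param models Character vector of model names (default: the seven core
#'   models).
#' @param priors Optional named list of prior data frames keyed by model name
#'   (defaults per model from [default_priors()]).
#' @param settings An [integration_settings()] object.
#' @param ... Passed to [log_marginal_likelihood()] (`memory_window_s`,
#'   `include_focal`).
#' @return An object of class `"model_comparison"`: a list with `table`
#'   (model, class, n_params, log2_evidence, rank, map), `best` (name of the
#'   top-ranked model), `pairwise` (matrix of log2 evidence ratios,
#'   row minus column) and `evidences` (the `"model_evidence"` objects).
#' @export
compare_models <- function(dataset, models = list_models()$name,
                           priors = NULL,
                           settings = integration_settings(), ...) {
  if (length(models) < 2L) stop("need at least two models", call. = FALSE)
  reg <- list_models(include_extensions = TRUE)
  unknown <- setdiff(models, reg$name)
  if (length(unknown))
    stop("unknown model(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  evs <- lapply(models, function(m) {
    pr <- if (!is.null(priors) && !is.null(priors[[m]])) priors[[m]]
          else default_priors(m)
    log_marginal_likelihood(m, dataset, prior = pr, settings = settings, ...)
  })
  names(evs) <- models
  vals <- vapply(evs, `[[`, numeric(1), "log2_evidence")
  ord <- order(-vals, seq_along(vals)) # stable: ties keep registry order
  tab <- data.frame(
    model = models,
    class = reg$class[match(models, reg$name)],
    n_params = reg$n_params[match(models, reg$name)],
    log2_evidence = vals,
    map = vapply(evs, function(e)
      paste(sprintf("%s=%.6g", names(e$map_params), e$map_params),
            collapse = ";"), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  pairwise <- outer(vals, vals, `-`)
  dimnames(pairwise) <- list(models, models)
  structure(list(table = tab, best = tab$model[1], pairwise = pairwise,
                 evidences = evs),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, digits = 3, ...) {
  cat("Model comparison (log2 marginal likelihoods)\n")
  tab <- x$table
  tab$log2_evidence <- round(tab$log2_evidence, digits)
  print(tab, row.names = FALSE)
  cat("Best model:", x$best, "\n")
  invisible(x)
}

.weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' Posterior parameter summaries
#'
#' Summarises the normalised posterior over the integration grid (or Monte
#' Carlo draws): per-parameter posterior mean, mode (MAP), central 95%
#' credible interval, and for positive multiplicative parameters the
#' posterior mean on the log2 scale.
#'
#' @param model Model name (must have at least one free parameter), or an
#'   existing `"model_evidence"` object (in which case `dataset` is ignored).
#' @param dataset A `"patch_dataset"`.
#' @param prior,settings,... Passed to [log_marginal_likelihood()].
#' @return A data frame with one row per parameter: `param`, `mean`, `mode`,
#'   `ci95_lo`, `ci95_hi`, `mean_log2` (`NA` for parameters with a uniform
#'   prior on the natural scale).
#' @export
posterior_summary <- function(model, dataset = NULL,
                              prior = NULL,
                              settings = integration_settings(), ...) {
  if (inherits(model, "model_evidence")) {
    ev <- model
  } else {
    if (length(model_params(model)) == 0L)
      stop("model ", model, " has no free parameters", call. = FALSE)
    if (is.null(prior)) prior <- default_priors(model)
    ev <- log_marginal_likelihood(model, dataset, prior = prior,
                                  settings = settings, ...)
  }
  if (is.null(ev$posterior))
    stop("model ", ev$model, " has no free parameters", call. = FALSE)
  post <- ev$posterior
  pars <- setdiff(names(post), "mass")
  rows <- lapply(pars, function(p) {
    x <- post[[p]]; w <- post$mass
    pr_dist <- ev$prior$dist[match(p, ev$prior$param)]
    data.frame(
      param = p,
      mean = sum(w * x),
      mode = ev$map_params[[p]],
      ci95_lo = .weighted_quantile(x, w, 0.025),
      ci95_hi = .weighted_quantile(x, w, 0.975),
      mean_log2 = if (identical(pr_dist, "log_uniform")) sum(w * log2(x))
                  else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
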