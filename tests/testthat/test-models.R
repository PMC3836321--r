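# Per-fish weights, side probabilities and sequential likelihoods for the
# competing social-response models.

test_that("the model registry holds seven core models plus the combined extension", {
  reg <- list_models()
  expect_identical(nrow(reg), 7L)
  expect_setequal(reg$name, c("M0", "S1", "S2", "S3", "S4", "D1", "D2"))
  expect_identical(reg$n_params[reg$name == "M0"], 0L)
  full <- list_models(include_extensions = TRUE)
  expect_identical(nrow(full), 8L)
  expect_identical(model_params("C1"), c("gamma", "alpha"))
  expect_identical(model_params("S4"), c("a", "s"))
})

test_that("per-fish weights follow each model's response rule", {
  st <- list(n_left = 1, n_right = 3)
  # null model: always 1
  expect_equal(per_fish_weight("M0", side = "L", state = st), 1)
  expect_equal(per_fish_weight("M0", side = "R", state = st), 1)
  # S1 binary response: fish on L has Delta = 3 - 0 = 3 > 0
  expect_equal(per_fish_weight("S1", c(gamma = 3), "L", st), 3)
  expect_equal(per_fish_weight("S1", c(gamma = 3), "R", st), 1 / 3)
  expect_equal(per_fish_weight("S1", c(gamma = 3), "L",
                               list(n_left = 2, n_right = 3)), 3)  # Delta = 2
  expect_equal(per_fish_weight("S1", c(gamma = 3), "L",
                               list(n_left = 3, n_right = 2)), 1)  # Delta = 0
  # S2 linear response with positivity floor
  expect_equal(per_fish_weight("S2", c(beta = 0.5), "L", st), 1 + 0.5 * 3)
  expect_equal(per_fish_weight("S2", c(beta = -1), "L", st), 1e-9)
  # S3 geometric response
  # Delta excludes the focal fish: Delta_L = 3 - 0 = 3, Delta_R = 1 - 2 = -1
  expect_equal(per_fish_weight("S3", c(g = 2), "L", st), 2^3)
  expect_equal(per_fish_weight("S3", c(g = 2), "R", st), 2^-1)
  # S4 logistic response saturates to 1 for Delta > 0 as s grows
  expect_equal(per_fish_weight("S4", c(a = 1, s = 64), "L", st), 1,
               tolerance = 1e-5)
  expect_equal(per_fish_weight("S4", c(a = 1, s = 1.5), "L",
                               list(n_left = 3, n_right = 2)), 0.5) # Delta = 0
  # D1 follow the last mover
  d1 <- list(n_left = 2, n_right = 2, last_direction = "L2R")
  expect_equal(per_fish_weight("D1", c(alpha = 2), "L", d1), 2)
  expect_equal(per_fish_weight("D1", c(alpha = 2), "R", d1), 1)
  expect_equal(per_fish_weight("D1", c(alpha = 2), "L",
                               list(n_left = 2, n_right = 2)), 1) # no last mover
  # D2 net recent flow
  d2 <- list(n_left = 2, n_right = 2, net_recent = 2)
  expect_equal(per_fish_weight("D2", c(alpha = 3), "L", d2), 9)
  expect_equal(per_fish_weight("D2", c(alpha = 3), "R", d2), 1 / 9)
  # C1 multiplies the S1 and D1 weights
  c1 <- list(n_left = 1, n_right = 3, last_direction = "L2R")
  expect_equal(per_fish_weight("C1", c(gamma = 3, alpha = 2), "L", c1), 6)
  # include_focal shifts Delta by one
  expect_equal(per_fish_weight("S3", c(g = 2), "L", st, include_focal = TRUE),
               2^2)
  expect_error(per_fish_weight("S1", c(gamma = 200), "L", st), "bounds")
  expect_error(per_fish_weight("D1", numeric(), "L", st), "missing parameter")
})

test_that("side probabilities normalise, zero out empty sides and match hand values", {
  expect_equal(side_probability("M0", state = list(n_left = 2, n_right = 1)),
               2 / 3)
  expect_equal(side_probability("D1", c(alpha = 2),
                                list(n_left = 1, n_right = 2,
                                     last_direction = "L2R")), 0.5)
  expect_equal(side_probability("S1", c(gamma = 2),
                                list(n_left = 0, n_right = 3)), 0)
  expect_equal(side_probability("S1", c(gamma = 2),
                                list(n_left = 3, n_right = 0)), 1)

  set.seed(11)
  models <- list_models(include_extensions = TRUE)$name
  for (m in models) {
    for (rep in 1:20) {
      G <- sample(3:6, 1)
      nl <- sample(0:G, 1)
      st <- list(n_left = nl, n_right = G - nl,
                 last_direction = sample(c("none", "L2R", "R2L"), 1),
                 net_recent = sample(-3:3, 1))
      th <- switch(m, M0 = numeric(),
                   S1 = c(gamma = exp(runif(1, -4, 4))),
                   S2 = c(beta = runif(1, -5, 5)),
                   S3 = c(g = exp(runif(1, -4, 4))),
                   S4 = c(a = exp(runif(1, -4, 4)), s = runif(1, 1.02, 60)),
                   D1 = c(alpha = exp(runif(1, -4, 4))),
                   D2 = c(alpha = exp(runif(1, -2, 2))),
                   C1 = c(gamma = exp(runif(1, -4, 4)),
                          alpha = exp(runif(1, -4, 4))))
      pl <- side_probability(m, th, st)
      st_m <- list(n_left = st$n_right, n_right = st$n_left,
                   last_direction = switch(st$last_direction, none = "none",
                                           L2R = "R2L", R2L = "L2R"),
                   net_recent = -st$net_recent)
      pr <- side_probability(m, th, st_m)
      # P(L) + P(R) = 1, where P(R) is P(L) of the mirrored state
      expect_equal(pl + pr, 1, tolerance = 1e-12)
      expect_gte(pl, 0); expect_lte(pl, 1)
    }
  }
})

test_that("log-likelihood reproduces the hand product and trivial cases", {
  tr <- crossing_trial("t1", 3, c("f1", "f2"),
                       events = data.frame(time_s = c(4, 5),
                                           fish_id = c("f1", "f3"),
                                           direction = c("L2R", "R2L")))
  # M0: P = 2/3 then 2/3
  expect_equal(log_likelihood("M0", dataset = tr), log2(4 / 9))
  expect_equal(log_likelihood("M0", dataset = tr), -1.1699, tolerance = 1e-4)
  expect_equal(log_likelihood("M0", dataset = tr, base = exp(1)), log(4 / 9))
  # empty dataset
  expect_identical(log_likelihood("M0", dataset = crossing_trial("e", 3, "f1")),
                   0)
  # forced moves contribute nothing
  forced <- crossing_trial("f", 2, "f1",
                           events = data.frame(time_s = c(1, 2),
                                               fish_id = c("f1", "f2"),
                                               direction = c("L2R", "R2L")))
  expect_equal(log_likelihood("S1", c(gamma = 4), forced),
               log2(side_probability("S1", c(gamma = 4),
                                     list(n_left = 1, n_right = 1))))
})

test_that("setting the response parameter to its neutral value reduces every model to M0", {
  ds <- reference_dataset(n_trials = 2, n_events = 120)
  ll0 <- log_likelihood("M0", dataset = ds)
  neutral <- list(S1 = c(gamma = 1), S2 = c(beta = 0), S3 = c(g = 1),
                  D1 = c(alpha = 1), D2 = c(alpha = 1),
                  C1 = c(gamma = 1, alpha = 1))
  for (m in names(neutral))
    expect_equal(log_likelihood(m, neutral[[m]], ds), ll0, tolerance = 1e-12)
})

test_that("relabelling left and right leaves every likelihood unchanged", {
  ds <- reference_dataset(n_trials = 3, n_events = 100)
  mir <- mirror_dataset(ds)
  cases <- list(M0 = numeric(), S1 = c(gamma = 2.5), S2 = c(beta = 0.7),
                S3 = c(g = 1.6), S4 = c(a = 2, s = 1.4), D1 = c(alpha = 3),
                D2 = c(alpha = 1.3), C1 = c(gamma = 2, alpha = 3))
  for (m in names(cases))
    expect_equal(log_likelihood(m, cases[[m]], mir),
                 log_likelihood(m, cases[[m]], ds), tolerance = 1e-9)
})

test_that("S4 is nearly linear for small occupancy differences and shallow steepness", {
  # states of 4- and 5-fish groups whose Delta (for the left side) is in -2..2
  states <- list(list(n_left = 3, n_right = 2), list(n_left = 2, n_right = 3),
                 list(n_left = 2, n_right = 2), list(n_left = 3, n_right = 3),
                 list(n_left = 4, n_right = 2), list(n_left = 2, n_right = 4))
  for (s_par in c(1.1, 1.3, 1.5)) {
    p4 <- vapply(states, function(st)
      side_probability("S4", c(a = 1, s = s_par), st), numeric(1))
    dev_for <- function(beta) {
      p2 <- vapply(states, function(st)
        side_probability("S2", c(beta = beta), st), numeric(1))
      max(abs(p4 - p2))
    }
    best <- stats::optimize(dev_for, c(0, 5))$objective
    expect_lt(best, 0.05)
  }
})

test_that("side probability responds monotonically to the social parameters", {
  al <- 2^seq(-3, 3, length.out = 13)
  st <- list(n_left = 2, n_right = 3, last_direction = "L2R")
  p_d1 <- vapply(al, function(a)
    side_probability("D1", c(alpha = a), st), numeric(1))
  expect_true(all(diff(p_d1) >= -1e-12))
  st_min <- list(n_left = 1, n_right = 4) # L is the minority side
  p_s1 <- vapply(al, function(g)
    side_probability("S1", c(gamma = g), st_min), numeric(1))
  expect_true(all(diff(p_s1) >= -1e-12))
})
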