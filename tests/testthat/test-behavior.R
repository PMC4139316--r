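test_that("Levy leg lengths follow the inverse-CDF power law", {
  # closed-form spot checks through the deterministic transform
  expect_equal(draw_levy_length(mu_levy = 2.4, a = 0), 1.0)
  expect_equal(draw_levy_length(mu_levy = 3, a = 0.75), 2.0)
  expect_equal(draw_levy_length(mu_levy = 2, a = c(0.5, 0.9)), c(2, 10))
  expect_error(draw_levy_length(mu_levy = 1), "mu_levy")
  expect_error(draw_levy_length(mu_levy = 2.4, a = 1), "a must")
})

test_that("engine Levy draws have the configured tail exponent", {
  # Hill/Pareto MLE oracle: for density ~ x^-mu with x >= 1,
  # mu_hat = 1 + n / sum(log x)
  x <- waggleforage:::cpp_levy_lengths(100000L, 2.4, 123L)
  expect_gte(min(x), 1.0)
  mu_hat <- 1 + length(x) / sum(log(x))
  expect_lt(abs(mu_hat - 2.4), 0.1)
  # and the R-surface sampler agrees with the same oracle
  set.seed(99)
  y <- draw_levy_length(100000, mu_levy = 3)
  expect_lt(abs(1 + length(y) / sum(log(y)) - 3), 0.1)
})

test_that("step costs distinguish resting from flight", {
  p <- sim_params()
  expect_equal(step_cost("idle", p), 0.04861)
  expect_equal(step_cost("flying", p), 0.43749)
  expect_equal(step_cost(c("waiting", "feeding"), p), c(0.04861, 0.43749))
  # a whole idle day costs 8640 steps of rest
  expect_equal(8640 * step_cost("idle", p), 420.0, tolerance = 1e-3)
  expect_error(step_cost("levitating", p), "unknown agent state")
})

test_that("trip value is linear in nectar quality", {
  p <- sim_params()
  expect_equal(trip_value(1.0, p), 282.25)
  expect_equal(trip_value(0, p), 0)
  expect_equal(trip_value(1.2, p), 338.7)
  expect_error(trip_value(-0.1, p), "quality")
})

test_that("mortality replaces agents in place at the configured rate", {
  p <- tiny_params(p_exit = 0, p_rs = 0)
  # m = 0: nobody dies
  r0 <- tiny_run(sim_params(t_day = 864L, forage_open = 14L,
                            forage_close = 418L, grid_half_extent = 20L,
                            n_exp_days = 6L, p_exit = 0, p_rs = 0, m = 0))
  expect_equal(sum(r0$days$deaths), 0)
  # m = 1: every agent is replaced every step, population constant
  r1 <- tiny_run(tiny_params(p_exit = 0, p_rs = 0, m = 1))
  expect_equal(unique(r1$days$deaths), r1$n_agents * 864L)
  # defaults: deaths ~ Binomial(N * t_day, m) per day
  r <- tiny_run(p, seed = 7)
  n_trials <- as.numeric(r$n_agents) * 864 * nrow(r$days)
  expected <- n_trials * p$m
  expect_lt(abs(sum(r$days$deaths) - expected), 3 * sqrt(expected) + 1)
})

test_that("idle colonies burn exactly the resting budget", {
  # with nobody leaving the nest, each day's net gain is -N * t_day * c_rest
  p <- tiny_params(p_exit = 0, p_rs = 0, m = 0)
  r <- tiny_run(p)
  expect_equal(unique(round(r$days$net_gain, 6)),
               round(-300 * 864 * 0.04861, 6))
  expect_equal(sum(r$days$trips_scout) + sum(r$days$trips_recruit), 0)
})

test_that("waiting recruits start scouting at rate p_rs", {
  # recruits can only leave via p_rs; count scouting activations through
  # trips at saturated density and certain detection
  p <- tiny_params(p_exit = 0, p_rs = 0.002, m = 0, d_patch = 0.5,
                   p_detect = 1, n_scouts = 0L, n_recruits = 300L,
                   persistent_recruits = FALSE)
  r <- tiny_run(p, condition = "NI", seed = 11)
  # every activation ends in a trip (dense forage); expected activations:
  # 300 waiting recruits x window steps x p_rs, minus time spent foraging.
  # Just check the rate is of the right order and strictly positive.
  trips <- sum(r$days$trips_recruit)
  expect_gt(trips, 0)
  upper <- 300 * (418 - 14) * 0.002 * nrow(r$days)
  expect_lt(trips, upper)
})

test_that("per-recruit site tenures never outlast patch longevity by much", {
  p <- tiny_params(a_max = 3L, d_patch = 0.2, p_detect = 1)
  r <- tiny_run(p, seed = 21)
  expect_true(all(r$tenures >= 1))
  # a site can be held at most a_max days plus a same-cell rebirth tail
  expect_lt(mean(r$tenures), p$a_max + 1)
})
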