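test_that("net trip value falls with distance and rises with quality", {
  p <- sim_params()
  # at zero distance only handling costs are subtracted
  handling <- p$t_patch_mean * p$c_rest * p$c_move_factor +
    p$t_nest * p$c_rest
  expect_equal(effective_value(1, 0, p), 282.25 - handling)
  q <- seq(0, 2, by = 0.1)
  d <- seq(0, 10000, by = 500)
  for (dd in d) expect_true(all(diff(effective_value(q, dd, p)) > 0))
  for (qq in q) expect_true(all(diff(effective_value(qq, d, p)) < 0))
})

test_that("dance probability is a calibrated logistic in trip value", {
  p <- sim_params()
  # solve for the quality whose net value hits the midpoint at 1 km
  q50 <- uniroot(function(q) effective_value(q, 1000, p) - p$dance_midpoint,
                 c(0, 5), tol = 1e-10)$root
  expect_equal(dance_probability(q50, 1000, p), 0.5, tolerance = 1e-9)
  # worthless forage is practically never danced for
  expect_lt(dance_probability(0, 0, p), 0.01)
  expect_lt(dance_probability(0, 10000, p), 0.01)
  # monotone on a grid, and the quality sigmoid right-shifts with distance
  qs <- seq(0, 2.5, by = 0.05)
  prev <- NULL
  for (dd in c(0, 2500, 5000, 10000)) {
    pd <- dance_probability(qs, dd, p)
    expect_true(all(diff(pd) > 0))
    if (!is.null(prev)) expect_true(all(pd <= prev))
    prev <- pd
  }
})

test_that("R and engine dance curves agree", {
  p <- sim_params()
  for (q in c(0.2, 0.8, 1.0, 1.3))
    for (d in c(0, 500, 2000, 8000))
      expect_equal(dance_probability(q, d, p),
                   waggleforage:::cpp_dance_probability(q, d, p),
                   tolerance = 1e-12)
})

test_that("forager influx suppresses dancing linearly down to the floor", {
  p <- sim_params()
  expect_equal(influx_factor(0, p), 1.0)
  expect_equal(influx_factor(10, p), 0.5)
  expect_equal(influx_factor(20, p), 0.0)
  expect_equal(influx_factor(25, p), influx_factor(20, p))
  pf <- sim_params(influx_floor = 0.4)
  expect_equal(influx_factor(10, pf), 0.7)
  expect_equal(influx_factor(100, pf), 0.4)
  expect_true(all(influx_factor(0:30, p) <= 1))
})

test_that("the return curve is the dance curve shifted up by 0.30", {
  p <- sim_params()
  # anchor: a source danced for half the time is revisited 80% of mornings
  q50 <- uniroot(function(q) dance_probability(q, 1500, p) - 0.5,
                 c(0, 5), tol = 1e-10)$root
  expect_equal(return_probability(q50, 1500, p), 0.8, tolerance = 1e-9)
  # unclamped region: constant +0.30 offset
  qs <- seq(0, 5, by = 0.05)
  pd <- dance_probability(qs, 2000, p)
  pr <- return_probability(qs, 2000, p)
  un <- pd < 0.69
  expect_equal(pr[un] - pd[un], rep(0.30, sum(un)))
  # clamp
  expect_equal(return_probability(5, 0, p), 1.0)
  expect_true(all(diff(pr) >= 0))
})

test_that("NI dances never transfer sites; SI dances copy the dancer's", {
  # under NI with p_rs = 0, recruits can only be activated to scout;
  # with detection disabled they can never acquire a site
  p <- tiny_params(p_rs = 0, p_detect = 0, d_patch = 0.3)
  r <- tiny_run(p, condition = "NI", seed = 31)
  expect_true(all(r$days$recruits_with_site == 0))
  expect_true(all(r$days$trips_recruit == 0))
  expect_length(r$tenures, 0)
  # under SI with self-scouting off (p_rs = 0), any recruit site must have
  # been copied from a dancer
  p2 <- tiny_params(p_rs = 0, p_detect = 1, d_patch = 0.3)
  r2 <- tiny_run(p2, condition = "SI", seed = 31)
  expect_gt(sum(r2$days$recruits_with_site), 0)
  expect_gt(sum(r2$days$trips_recruit), 0)
})

test_that("recruitment penalties are charged once per recruitment event", {
  # forced dancing and recruitment: penalties tally one c_recruit per
  # first arrival, so penalties / c_recruit is an integer count and
  # cannot exceed recruit trips
  p <- tiny_params(d_patch = 0.3, p_detect = 1, dance_midpoint = -1e6,
                   dance_slope = 10)
  r <- tiny_run(p, seed = 41)
  n_pen <- sum(r$days$penalties) / p$c_recruit
  expect_equal(n_pen, round(n_pen))
  expect_gt(n_pen, 0)
  expect_lte(n_pen, sum(r$days$trips_recruit) + sum(r$days$deaths))
})

test_that("free certain recruitment mobilises more recruits than default", {
  p1 <- tiny_params(d_patch = 0.2, p_detect = 1)
  p2 <- tiny_params(d_patch = 0.2, p_detect = 1, p_dance = 1, c_recruit = 0)
  r1 <- tiny_run(p1, seed = 51)
  r2 <- tiny_run(p2, seed = 51)
  expect_gt(sum(r2$days$trips_recruit), sum(r1$days$trips_recruit))
  expect_equal(sum(r2$days$penalties), 0)
})
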