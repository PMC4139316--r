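test_that("relative benefit is plain percentage arithmetic", {
  expect_equal(relative_benefit(c(100, 100), c(100, 100)), 0)
  expect_equal(relative_benefit(121.6, 100), 21.6)
  expect_equal(relative_benefit(84.2, 100), -15.8)
  expect_equal(relative_benefit(c(110, 130), c(90, 110)), 20)
  expect_warning(b <- relative_benefit(10, c(-5, 5)), "not positive")
  expect_true(is.na(b))
  expect_error(relative_benefit(numeric(), 1), "non-empty")
})

test_that("replicate summaries use the standard error over runs", {
  s <- replicate_summary(c(2, 4, 6, 8))
  expect_equal(s$mean, 5)
  expect_equal(s$se, sd(c(2, 4, 6, 8)) / 2)
  expect_equal(s$n, 4)
})

test_that("per-capita efficiency nets deliveries against role costs", {
  p <- sim_params(n_scouts = 1L, n_recruits = 1L)
  # hand-built ledger: one experimental day, one recruit delivery of
  # 282.25 J against a full idle day of resting cost plus one penalty
  days <- data.frame(
    day = 1:2, acclim = c(TRUE, FALSE), net_gain = 0,
    deliv_scout = c(0, 0), deliv_recruit = c(999, 282.25),
    cost_scout = c(0, 420), cost_recruit = c(999, 420),
    penalties = c(0, 325)
  )
  expect_equal(per_capita_efficiency(days, p, "recruit"),
               282.25 - 420 - 325)
  expect_equal(per_capita_efficiency(days, p, "scout"), -420)
  expect_equal(per_capita_efficiency(days, p, "recruit", gross = TRUE),
               282.25)
  # acclimatization row (with its sentinel 999s) was excluded throughout
})

test_that("Poisson persistency matches the closed-form MLE and fitdistr", {
  expect_equal(persistency_poisson(rep(1, 10))$mean, 1)
  r <- persistency_poisson(c(1, 2, 3, 2))
  expect_equal(r$mean, 2)
  expect_equal(r$se, sqrt(2 / 4))
  expect_error(persistency_poisson(integer()), "no tenure")
  expect_error(persistency_poisson(c(1, 0)), ">= 1")
  # independent oracle: MASS::fitdistr numeric ML fit
  set.seed(4)
  x <- rpois(500, 2.7) + 1L
  ours <- persistency_poisson(x)
  oracle <- MASS::fitdistr(x, "Poisson")
  expect_equal(ours$mean, unname(oracle$estimate), tolerance = 1e-6)
  expect_equal(ours$se, unname(oracle$sd), tolerance = 1e-6)
})

test_that("carry-over profiles index days within condition blocks", {
  # synthetic two-run table with a 2-day cycle and a known gradient
  mk <- function(run, gains) {
    data.frame(run = run, day = 1:8,
               condition = c("SI", "SI", "SI", "SI", "NI", "NI", "SI", "SI"),
               acclim = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                          FALSE),
               net_gain = gains)
  }
  days <- rbind(mk(1, c(0, 0, 10, 8, 6, 2, 9, 9)),
                mk(2, c(0, 0, 12, 10, 8, 4, 11, 9)))
  cp <- carryover_profile(days)
  ni1 <- cp[cp$condition == "NI" & cp$position == 1, ]
  ni2 <- cp[cp$condition == "NI" & cp$position == 2, ]
  expect_equal(ni1$mean_gain, 7)   # first NI day inherits SI momentum
  expect_equal(ni2$mean_gain, 3)
  expect_equal(ni1$n_days, 2)
  si1 <- cp[cp$condition == "SI" & cp$position == 1, ]
  expect_equal(si1$mean_gain, mean(c(10, 9, 12, 11)))
})

test_that("preset suites enumerate the published experiment grids", {
  e1 <- preset_experiments("experiment1")
  expect_length(e1, 12)
  expect_setequal(unique(vapply(e1, function(e) e$params$d_patch, 0)),
                  c(0.1, 0.05, 0.01))
  e2 <- preset_experiments("experiment2")
  expect_length(e2, 16)
  expect_setequal(unique(vapply(e2, function(e) e$params$a_max, 0L)),
                  c(1L, 7L, 14L, 28L))
  expect_true(all(vapply(e2, function(e) e$params$d_patch, 0) == 0.05))
  nc <- preset_experiments("no_cost")
  expect_length(nc, 4)
  expect_true(all(vapply(nc, function(e) e$params$p_dance, 0) == 1))
  expect_true(all(vapply(nc, function(e) e$params$c_recruit, 0) == 0))
  sens <- preset_experiments("sensitivity")
  expect_gt(length(sens), 10)
  expect_error(preset_experiments("bogus"))
})
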