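test_that("immunization schedule follows the closed-form linear decrement", {
  s <- immunization_schedule(initial = 10, decrement = 2, period_h = 6)
  ins <- immunization_insertions(s)
  expect_equal(ins$t_h, c(0, 6, 12, 18, 24))
  expect_equal(ins$count, c(10, 8, 6, 4, 2))

  one <- immunization_insertions(immunization_schedule(10, 10, 6))
  expect_equal(nrow(one), 1L)
  expect_equal(one$count, 10)

  # longer period = weaker immunization: half the DCs over any fixed window
  fast <- immunization_insertions(immunization_schedule(10, 0, 6, window_h = 47))
  slow <- immunization_insertions(immunization_schedule(10, 0, 12, window_h = 47))
  expect_equal(sum(slow$count), sum(fast$count) / 2)

  expect_error(immunization_schedule(10, 2, period_h = 0))
})

test_that("smooth_rate implements the trailing rectangular window", {
  grid <- seq(0, 100, by = 0.5)
  expect_true(all(smooth_rate(numeric(0), 24, grid) == 0))

  # a death at t0 is visible at times t with t0 in (t - w, t], i.e. [t0, t0+w)
  r <- smooth_rate(10, 24, grid)
  inside <- grid >= 10 & grid < 34
  expect_true(all(r[inside] == 1 / 24))
  expect_true(all(r[!inside] == 0))

  # Poisson events at rate lambda: long-window smoothed rate approaches lambda
  set.seed(21)
  lambda <- 3
  ev <- cumsum(rexp(5000, lambda))
  r <- smooth_rate(ev, 200, max(ev) / 2)
  expect_lt(abs(r - lambda) / lambda, 0.1)
})

test_that("score_course thresholds rates and truncates at death", {
  rule <- scoring_rule(24, c(1, 2, 3, 4, 5))
  grid <- 1:100
  low <- rep(0.5, 100)
  cs <- score_course(low, rule, grid)
  expect_true(all(cs$score == 0))
  expect_false(attr(cs, "died"))

  rate <- c(rep(0, 10), seq(0.5, 6, length.out = 40), rep(6, 50))
  cs <- score_course(rate, rule, grid)
  expect_true(attr(cs, "died"))
  expect_equal(attr(cs, "death_time_h"), grid[which(rate >= 5)[1]])
  expect_equal(max(cs$score), 5L)
  expect_equal(nrow(cs), which(rate >= 5)[1])

  # monotone rates give monotone nondecreasing scores
  set.seed(22)
  for (i in 1:20) {
    r <- cumsum(runif(50, 0, 0.3))
    th <- sort(runif(5, 0, max(r)))
    if (any(diff(th) <= 0)) next
    cs <- score_course(r, scoring_rule(24, th), 1:50)
    expect_true(all(diff(cs$score) >= 0))
  }

  expect_error(scoring_rule(24, c(1, 2, 2, 4, 5)))
})

test_that("episode extraction applies the remission-gap rule", {
  g <- 1:200  # hourly grid
  none <- extract_outcomes(rep(0L, 200), g)
  expect_equal(none$n_episodes, 0L)
  expect_equal(none$relapse_count, 0L)
  expect_equal(none$max_score, 0L)

  one <- extract_outcomes(c(rep(0L, 50), rep(2L, 60), rep(0L, 90)), g)
  expect_equal(one$n_episodes, 1L)
  expect_equal(one$relapse_count, 0L)
  expect_equal(one$first_episode_duration_d, 60 / 24)

  # two sick blocks separated by >= 24 h of score 0: two episodes, one relapse
  sc <- c(rep(0L, 20), rep(1L, 40), rep(0L, 30), rep(2L, 40), rep(0L, 70))
  two <- extract_outcomes(sc, g)
  expect_equal(two$n_episodes, 2L)
  expect_equal(two$relapse_count, 1L)
  expect_equal(two$episodes$max_score, c(1L, 2L))

  # a sub-24 h dip does not end an episode
  sc <- c(rep(0L, 20), rep(1L, 40), rep(0L, 10), rep(2L, 40), rep(0L, 90))
  merged <- extract_outcomes(sc, g)
  expect_equal(merged$n_episodes, 1L)
  expect_equal(merged$first_episode_duration_d, 90 / 24)
})

test_that("episode duration for fatal runs extends to end of observation", {
  rule <- scoring_rule(24, c(1, 2, 3, 4, 5))
  grid <- 1:300
  rate <- c(rep(0, 99), seq(1, 6, length.out = 100), rep(6, 101))
  cs <- score_course(rate, rule, grid)
  out <- extract_outcomes(cs, horizon_h = 1200)
  expect_true(out$died)
  expect_equal(out$first_episode_duration_d, (1200 - out$episodes$onset_h[1]) / 24)
})

test_that("calibration recovers a planted scoring rule with objective zero", {
  set.seed(23)
  ev_a <- synth_death_events(6, "monophasic", peak_rate_per_h = 2)
  ev_b <- synth_death_events(6, "relapsing", peak_rate_per_h = 3)
  grid <- seq(1, 1200, by = 2)
  cand <- lapply(1:8, function(i) sort(runif(5, 0.1, 4)))
  cand <- Filter(function(th) all(diff(th) > 0), cand)
  planted <- cand[[3]]
  planted_rule <- scoring_rule(24, planted)
  targets <- list(
    change_freq = c(scoring_group_stats(ev_a, planted_rule, grid)$change_freq,
                    scoring_group_stats(ev_b, planted_rule, grid)$change_freq),
    max_props = rbind(scoring_group_stats(ev_a, planted_rule, grid)$max_props,
                      scoring_group_stats(ev_b, planted_rule, grid)$max_props)
  )
  fit <- calibrate_scoring(ev_a, ev_b, windows_h = c(12, 24), threshold_sets = cand,
                           targets = targets, grid_h = grid)
  expect_equal(fit$objective, 0)
  expect_equal(fit$rule$window_h, 24)
  expect_equal(fit$rule$thresholds, planted)

  # single candidate: returned regardless of fit, with its objective
  solo <- calibrate_scoring(ev_a, ev_b, windows_h = 24,
                            threshold_sets = cand[1], targets = targets,
                            grid_h = grid)
  expect_equal(solo$rule$thresholds, cand[[1]])
  expect_gt(solo$objective, 0)

  # dominant criterion-3 weight forces the two per-experiment sets to coincide
  dom <- calibrate_scoring(ev_a, ev_b, windows_h = 24, threshold_sets = cand,
                           targets = targets, grid_h = grid,
                           weights = c(1e-6, 1e-6, 1e6))
  expect_equal(dom$per_experiment[[1]], dom$per_experiment[[2]])

  expect_error(calibrate_scoring(ev_a, ev_b, numeric(0), cand, targets, grid))
})
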