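test_that("boundary walking finds the first deviating value on each side", {
  vals <- c(1, 2, 5, 10, 20, 50, 100)
  dev <- c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE)
  b <- find_boundaries(vals, default = 10, deviates = dev)
  expect_equal(b$LB, 2)
  expect_equal(b$UB, 50)

  none <- find_boundaries(vals, 10, rep(FALSE, 7))
  expect_true(is.nan(none$LB) && is.nan(none$UB))

  only_up <- find_boundaries(vals, 10, vals >= 100)
  expect_true(is.nan(only_up$LB))
  expect_equal(only_up$UB, 100)

  expect_error(find_boundaries(vals, 11, dev), "default")
})

test_that("robustness indices follow the percentage-of-default arithmetic", {
  idx <- robustness_index(LB = 5, UB = 20, default = 10)
  expect_equal(idx$LI, 50)
  expect_equal(idx$UI, 100)
  expect_equal(idx$RI, 50)

  idx <- robustness_index(LB = 9, UB = NaN, default = 10)
  expect_equal(idx$RI, 10)
  expect_true(is.nan(idx$UI))

  idx <- robustness_index(NaN, NaN, 10)
  expect_true(is.nan(idx$RI))

  z <- robustness_index(LB = -2, UB = 3, default = 0)
  expect_true(is.nan(z$RI))
  expect_equal(z$abs_lower, 2)
  expect_equal(z$abs_upper, 3)
})

test_that("the A-test rule and the EAE mean rule trigger independently", {
  set.seed(31)
  ctrl <- rnorm(200, 0, 3)
  # mean shifted by 1.2 score points but heavily overlapping: A-test not large
  shifted <- rnorm(200, 1.25, 3)
  expect_false(classify_effect(a_test(shifted, ctrl)$A) == "large")
  expect_true(response_deviation(shifted, ctrl, eae_response = TRUE))
  expect_false(response_deviation(shifted, ctrl, eae_response = FALSE))
  # disjoint distributions with a sub-1.0 mean shift: A-test rule only
  tight <- rnorm(200, 0.5, 0.01)
  tight_ctrl <- rnorm(200, 0, 0.01)
  expect_true(response_deviation(tight, tight_ctrl, eae_response = FALSE))
  expect_true(response_deviation(tight, tight_ctrl, eae_response = TRUE))
})

test_that("planted deviation boundaries are recovered exactly", {
  set.seed(32)
  vals <- c(0.1, 0.2, 0.5, 1, 2, 5, 10)
  for (trial in 1:20) {
    lb_i <- sample(0:3, 1)   # deviation holds at indices <= lb_i (0 = none)
    ub_i <- sample(5:8, 1)   # deviation holds at indices >= ub_i (8 = none)
    gen <- function(v) {
      i <- match(v, vals)
      if (i <= lb_i || i >= ub_i) rnorm(60, 50, 1) else rnorm(60, 0, 1)
    }
    resp <- lapply(vals, function(v) data.frame(CD4Th1Max = gen(v)))
    rec <- parameter_robustness(resp, vals, default = 1)
    expect_equal(rec$LB, if (lb_i >= 1) vals[lb_i] else NaN)
    expect_equal(rec$UB, if (ub_i <= 7) vals[ub_i] else NaN)
    idx <- robustness_index(rec$LB, rec$UB, 1)
    expect_equal(rec$RI, idx$RI)
  }
})

test_that("refining a sweep never moves a boundary away from the default", {
  crit <- function(v) abs(log10(v)) >= 0.7   # deterministic deviation rule
  coarse <- c(0.1, 1, 10)
  fine <- sort(c(coarse, 0.3, 0.5, 3, 5))
  b_c <- find_boundaries(coarse, 1, vapply(coarse, crit, logical(1)))
  b_f <- find_boundaries(fine, 1, vapply(fine, crit, logical(1)))
  expect_lte(abs(b_f$UB - 1), abs(b_c$UB - 1))
  expect_lte(abs(1 - b_f$LB), abs(1 - b_c$LB))
})

test_that("the global rank table orders parameters by summed ranks", {
  recs <- expand.grid(parameter = c("a", "b", "c"),
                      response = c("r1", "r2"), stringsAsFactors = FALSE)
  recs$RI <- c(10, 50, NaN,   # r1: a < b < c(NaN)
               5, 100, NaN)   # r2: a < b < c(NaN)
  tab <- rank_table(recs)
  expect_equal(tab$parameter, c("a", "b", "c"))
  expect_equal(tab$total, c(2, 4, 6))
  expect_true(is.nan(tab[tab$parameter == "c", "r1"]))

  solo <- rank_table(data.frame(parameter = "a",
                                response = c("r1", "r2"), RI = c(3, NaN)))
  expect_equal(solo$total, 2)

  # ties take the average rank
  t2 <- rank_table(data.frame(parameter = c("a", "b"), response = "r1",
                              RI = c(7, 7)))
  expect_equal(t2$total, c(1.5, 1.5))
})

test_that("sweep_parameter validates parameters and derives per-value seeds", {
  cfg <- eae_config()
  seen <- list()
  stub <- function(config, n, master_seed) {
    seen[[length(seen) + 1]] <<- list(v = config$tcell_aicd_mean_h,
                                      seed = master_seed)
    data.frame(CD4Th1Max = rnorm(n, 100, 10))
  }
  sw <- sweep_parameter("tcell_aicd_mean_h", c(48, 96, 192), n_reps = 20,
                        base_config = cfg, master_seed = 7, runner = stub)
  expect_equal(length(sw), 3L)
  expect_equal(vapply(seen, `[[`, numeric(1), "v"), c(48, 96, 192))
  expect_equal(length(unique(vapply(seen, `[[`, numeric(1), "seed"))), 3L)
  expect_error(sweep_parameter("no_such", 1, 5, cfg), "unknown")
  expect_error(sweep_parameter("regulatory_efficacy", 2, 5, cfg), "legal range")

  # sweep containing only the default compares the control with itself
  rec <- parameter_robustness(sw["96"], 96, default = 96)
  expect_true(is.nan(rec$RI))
})
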