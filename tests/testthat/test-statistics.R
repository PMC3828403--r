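test_that("a_test equals the exhaustive pairwise oracle on random small samples", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(1:8, 1)
    m <- sample(1:8, 1)
    x <- sample(0:5, n, replace = TRUE)  # heavy ties
    y <- sample(0:5, m, replace = TRUE)
    expect_equal(a_test(x, y)$A, oracle_a_pairwise(x, y), tolerance = 1e-12)
  }
})

test_that("a_test satisfies complementarity A(x,y) + A(y,x) = 1 under ties", {
  set.seed(12)
  for (i in 1:50) {
    x <- rpois(sample(2:30, 1), 3)
    y <- rpois(sample(2:30, 1), 3)
    expect_equal(a_test(x, y)$A + a_test(y, x)$A, 1, tolerance = 1e-12)
  }
  expect_equal(a_test(1:5, 1:5)$A, 0.5)
  expect_equal(a_test(6:8, 1:3)$A, 1)
  expect_error(a_test(numeric(0), 1:3))
})

test_that("effect bands reproduce the published cutoffs at their boundaries", {
  expect_equal(classify_effect(0.5), "none")
  expect_equal(classify_effect(0.44), "small")
  expect_equal(classify_effect(0.56), "small")
  expect_equal(classify_effect(0.36), "medium")
  expect_equal(classify_effect(0.64), "medium")
  expect_equal(classify_effect(0.29), "large")
  expect_equal(classify_effect(0.71), "large")
  expect_equal(classify_effect(0.4401), "none")
  expect_equal(classify_effect(0.5599), "none")
  # symmetry: classify(A) == classify(1 - A)
  aa <- seq(0, 1, by = 0.01)
  expect_equal(classify_effect(aa), classify_effect(1 - aa))
  expect_error(classify_effect(1.2))
})

test_that("mann_whitney_u matches the enumeration oracle on tied small samples", {
  set.seed(13)
  for (i in 1:60) {
    n <- sample(2:7, 1)
    m <- sample(2:7, 1)
    x <- sample(0:3, n, replace = TRUE)
    y <- sample(0:3, m, replace = TRUE)
    got <- mann_whitney_u(x, y, method = "exact")
    expect_equal(got$p_value, oracle_mwu_exact(x, y), tolerance = 1e-10)
  }
})

test_that("mann_whitney_u agrees with wilcox.test on tie-free samples", {
  set.seed(14)
  for (i in 1:30) {
    x <- rnorm(sample(3:8, 1))
    y <- rnorm(sample(3:8, 1))
    got <- mann_whitney_u(x, y, method = "exact")
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
  # large-sample approximate path against wilcox.test's normal approximation
  x <- rnorm(60, 0.3)
  y <- rnorm(55)
  got <- mann_whitney_u(x, y, method = "approx")
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("mann_whitney_u handles the episode-count encoding and degenerate ties", {
  # 500 runs all with one episode vs 400 one-episode + 100 two-episode runs:
  # the raw counts are consumed directly and the difference is significant.
  x <- rep(1, 500)
  y <- c(rep(1, 400), rep(2, 100))
  res <- mann_whitney_u(x, y)
  expect_lt(res$p_value, 0.001)
  # identical constant samples: no evidence of difference
  expect_equal(mann_whitney_u(rep(3, 10), rep(3, 12))$p_value, 1)
})

test_that("fisher_exact matches hypergeometric enumeration for small margins", {
  set.seed(15)
  for (i in 1:80) {
    tab <- matrix(sample(0:6, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact(tab)$p_value, oracle_fisher_exact(tab),
                 tolerance = 1e-9)
  }
  expect_equal(fisher_exact(matrix(c(0, 10, 0, 12), 2, byrow = TRUE))$p_value, 1)
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)))
})

test_that("group summaries report medians, IQRs and rates as hand-computed", {
  out <- data.frame(
    max_score = c(0, 1, 2, 3, 5, 1, 0, 2, 1, 4),
    n_episodes = c(0, 1, 1, 1, 1, 2, 0, 1, 1, 1),
    relapse_count = c(0, 0, 0, 0, 0, 1, 0, 0, 0, 0),
    died = c(rep(FALSE, 4), TRUE, rep(FALSE, 5)),
    first_episode_duration_d = c(NA, 8, 10, 12, 50, 14, NA, 9, 11, 20)
  )
  s <- summarize_group(out)
  expect_equal(s$n, 10)
  expect_equal(s$mortality_pct, 10)
  expect_equal(s$relapse_pct, 10)
  med <- s$metrics$median[s$metrics$metric == "max_score"]
  expect_equal(med, median(out$max_score))
  one <- summarize_group(out[2, ])
  expect_equal(one$metrics$iqr[one$metrics$metric == "max_score"], 0)
})

test_that("compare_groups wires A-test, U test and Fisher together", {
  set.seed(16)
  ctrl <- data.frame(max_score = rep(1:2, each = 25),
                     n_episodes = rep(1, 50),
                     relapse_count = rep(0, 50),
                     first_episode_duration_d = rnorm(50, 10, 1),
                     died = rep(c(TRUE, FALSE), c(5, 45)))
  expt <- data.frame(max_score = rep(3:4, each = 25),
                     n_episodes = rep(c(1, 2), c(30, 20)),
                     relapse_count = rep(c(0, 1), c(30, 20)),
                     first_episode_duration_d = rnorm(50, 20, 1),
                     died = rep(c(TRUE, FALSE), c(20, 30)))
  cmp <- compare_groups(ctrl, expt)
  tst <- cmp$tests
  expect_equal(tst$effect[tst$metric == "max_score"], "large")
  expect_equal(tst$A[tst$metric == "max_score"], 1)
  expect_true(all(tst$p <= 0.05))
  expect_lt(cmp$mortality$p_value, 0.01)
  expect_equal(cmp$mortality$table["experimental", "died"], 20)
})
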