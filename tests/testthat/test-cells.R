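test_that("state durations are normal draws clamped at zero", {
  set.seed(51)
  expect_equal(draw_duration(5, 8, 0), rep(8, 5))

  d <- draw_duration(1e5, 8, 1)
  expect_true(all(d >= 0))
  expect_lt(abs(mean(d) - 8), 0.03)        # CLT band at n = 1e5
  expect_lt(abs(sd(d) - 1), 0.03)

  # mean 0: the clamp dominates; E[max(N(0,1),0)] = 1/sqrt(2*pi)
  z <- draw_duration(1e5, 0, 1)
  expect_true(all(z >= 0))
  expect_lt(abs(mean(z) - 1 / sqrt(2 * pi)), 0.01)

  expect_error(draw_duration(10, 8, -1), ">= 0")
})

test_that("binding succeeds with probability p times the modifier product", {
  set.seed(52)
  expect_false(any(attempt_binding(1000, 0.9, modifiers = 0)))  # full blockade
  expect_true(all(attempt_binding(1000, 1)))
  f <- mean(attempt_binding(1e5, 0.4, modifiers = 0.5))
  expect_lt(abs(f - 0.2), 3 * sqrt(0.2 * 0.8 / 1e5))
  expect_error(attempt_binding(10, 0.5, modifiers = 3), "outside")
})

test_that("binding rates match the closed form over a probability grid", {
  set.seed(53)
  for (p in c(0.05, 0.3, 0.7)) {
    for (m in list(numeric(0), 0.5, c(0.8, 0.5))) {
      prob <- p * prod(m)
      f <- mean(attempt_binding(1e5, p, m))
      expect_lt(abs(f - prob), 3 * sqrt(prob * (1 - prob) / 1e5) + 1e-12)
    }
  }
})

test_that("CD8Treg killing respects regulatory efficacy and the Qa-1 window", {
  set.seed(54)
  expect_true(all(cd8treg_kill_attempt(100, 1)))
  expect_false(any(cd8treg_kill_attempt(100, 0)))
  f <- mean(cd8treg_kill_attempt(1e5, 0.03))
  expect_lt(abs(f - 0.03), 3 * sqrt(0.03 * 0.97 / 1e5))
  expect_error(cd8treg_kill_attempt(1, 0.5, qa1_active = FALSE), "Qa-1")
  expect_error(cd8treg_kill_attempt(1, 1.2), "\\[0, 1\\]")
})

test_that("no CD4Th1 is ever killed after its Qa-1 window has expired", {
  # instrumented contract over a full disease course with active regulation
  r <- simulate_run(eae_config(horizon_d = 30), 55)
  expect_gt(r$counters$kills_cd8, 50)
  expect_identical(r$counters$kills_expired_qa1, 0)
})

test_that("polarization follows the local type-1 : type-2 cytokine balance", {
  # type-2-dominated lymphoid tissue: priming yields CD4Th2
  cfg2 <- eae_config(horizon_d = 8, dc_type1_secretion_per_h = 0,
                     basal_type2_per_h = 0.5)
  r2 <- simulate_run(cfg2, 56)
  th <- apply(r2$counts[, , c("CD4Th1", "CD4Th2")], 3, max)
  expect_gt(th["CD4Th2"], th["CD4Th1"])

  # type-1-dominated (control wiring): CD4Th1 dominates
  r1 <- simulate_run(eae_config(horizon_d = 8), 56)
  th <- apply(r1$counts[, , c("CD4Th1", "CD4Th2")], 3, max)
  expect_gt(th["CD4Th1"], th["CD4Th2"])
})

test_that("the regulatory circuit is wired through phagocytosis and priming", {
  r <- simulate_run(eae_config(horizon_d = 20), 57)
  # apoptotic CD4Th1 are presented for Treg priming, mainly in the spleen
  expect_gt(sum(r$priming["CD4Treg", ]), 0)
  expect_gt(sum(r$priming["CD8Treg", ]), 0)
  expect_equal(unname(r$priming["CD8Treg", "CNS"]), 0)
  expect_gt(r$priming["CD8Treg", "SPLEEN"], sum(r$priming["CD8Treg", ]) / 2)
  # Qa-1 is expressed by freshly differentiated CD4Th1 effectors
  set.seed(57)
  w <- eae_world(eae_config(horizon_d = 10))
  step_world(w, 1700)  # ~day 7: differentiation ongoing
  cells <- world_cells(w)
  th1_eff <- cells[cells$population == "CD4Th1" & cells$state == 2, ]
  expect_gt(nrow(th1_eff), 0)
  expect_gt(sum(th1_eff$qa1_active), 0)
})

test_that("regulation intensity is monotone in regulatory efficacy", {
  # killed fraction of minted CD4Th1, paired seeds, 6 replicates per level
  kf <- sapply(c(0, 0.25, 0.5, 1), function(eff) {
    cfg <- eae_config(horizon_d = 20, regulatory_efficacy = eff)
    mean(sapply(1:6, function(i) {
      r <- simulate_run(cfg, derive_seed(3, "kf", i))
      r$counters$kills_cd8 / max(r$counters$th1_minted, 1)
    }))
  })
  expect_equal(kf[1], 0)              # no kills without efficacy
  expect_true(all(diff(kf) > -0.02))  # nondecreasing up to sampling jitter
  expect_gt(kf[4], 0.4)
})

test_that("neurons killed by the demyelinating agent are replaced", {
  r <- simulate_run(eae_config(horizon_d = 50), 58)
  expect_gt(length(r$death_events_h), 30)
  nt <- dim(r$counts)[1]
  # after recovery the CNS neuron census is restored (a few replacements
  # may still be pending)
  expect_gte(r$counts[nt, "CNS", "Neuron"], 0.95 * 450)
  # neurons never appear outside the CNS
  expect_true(all(r$counts[, c("CLN", "CIRC", "SPLEEN", "SLO"), "Neuron"] == 0))
})
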