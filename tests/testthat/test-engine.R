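# A world with no immunization, no residents and no recruitment: nothing
# should happen except the clock.
empty_config <- function(...) {
  eae_config(imm_dc_initial = 0, imm_dc_decrement = 0, n_neurons = 1,
             n_microglia = 0, n_cns_dc = 0, n_splenic_dc = 0, n_cln_dc = 0,
             th_naive_target = 0, treg4_naive_target = 0,
             treg8_naive_target = 0, recruit_per_h = 0, horizon_d = 2, ...)
}

test_that("diffusion and decay obey their closed-form contracts", {
  u <- matrix(2.5, 6, 6)
  expect_equal(diffuse_decay(u, D = 0.5, lambda = 0, dt = 0.1), u)

  # D = 0: pure exponential decay; lambda chosen for a half-life of one step
  f <- matrix(runif(16), 4, 4)
  half <- diffuse_decay(f, D = 0, lambda = log(2) / 0.1, dt = 0.1)
  expect_equal(half, f / 2, tolerance = 1e-12)

  # closed boundary conserves mass over 100 steps at zero decay
  set.seed(41)
  f <- matrix(runif(64, 0, 10), 8, 8)
  g <- f
  for (i in 1:100) g <- diffuse_decay(g, D = 0.5, lambda = 0, dt = 0.1)
  expect_equal(sum(g), sum(f), tolerance = 1e-9)
  expect_true(all(g >= 0))
  # toroidal wrap also conserves mass
  g2 <- f
  for (i in 1:50) g2 <- diffuse_decay(g2, 0.5, 0, 0.1, toroidal = TRUE)
  expect_equal(sum(g2), sum(f), tolerance = 1e-9)

  expect_error(diffuse_decay(matrix(-1, 2, 2), 0.1, 0, 0.1), "nonneg|>= 0")
  expect_error(diffuse_decay(matrix(1, 2, 2), D = 4, lambda = 0, dt = 0.1),
               "unstable")
})

test_that("the random walk is uniform over the Moore neighbourhood", {
  set.seed(42)
  # 1x1 grid: nowhere to go
  for (i in 1:5) expect_equal(random_walk_step(0, 0, 1, 1), c(0L, 0L))

  # interior cell: chi-square against uniform over the 8 neighbours
  draws <- t(replicate(10000, random_walk_step(5, 5, 11, 11)))
  key <- paste(draws[, 1], draws[, 2])
  expect_equal(length(unique(key)), 8L)
  expect_gt(chisq.test(table(key))$p.value, 1e-4)

  # closed corner: never leaves the grid
  corner <- t(replicate(500, random_walk_step(0, 0, 4, 4)))
  expect_true(all(corner >= 0 & corner <= 3))
  # toroidal corner wraps to the opposite edge
  wrapped <- t(replicate(500, random_walk_step(0, 0, 4, 4, toroidal = TRUE)))
  expect_true(any(wrapped == 3))
})

test_that("a vacuous step advances the clock and changes nothing else", {
  set.seed(43)
  w <- eae_world(empty_config())
  before <- world_cells(w)
  step_world(w, 1)
  st <- world_state(w)
  expect_equal(st$step_index, 1)
  expect_equal(st$t, st$dt_h)
  after <- world_cells(w)
  expect_equal(nrow(after), nrow(before))  # a lone immobile neuron
  expect_equal(after$pop, before$pop)
})

test_that("stepping a terminated run signals a terminal-state error", {
  set.seed(44)
  w <- eae_world(empty_config(horizon_d = 1))
  n <- world_state(w)$n_steps
  step_world(w, n)
  expect_error(step_world(w, 1), "terminated|horizon")
})

test_that("zero movement probability freezes all positions", {
  set.seed(45)
  cfg <- eae_config(cell_motility = 0, naive_exit_per_h = 0,
                    effector_exit_per_h = 0, horizon_d = 2,
                    imm_dc_initial = 0, imm_dc_decrement = 0)
  w <- eae_world(cfg)
  before <- world_cells(w)
  step_world(w, 100)
  after <- world_cells(w)
  live <- seq_len(min(nrow(before), nrow(after)))
  expect_equal(after$x[live], before$x[live])
  expect_equal(after$y[live], before$y[live])
})

test_that("identical seed and configuration reproduce a run exactly", {
  cfg <- eae_config(horizon_d = 8)
  a <- simulate_run(cfg, 99)
  b <- simulate_run(cfg, 99)
  expect_identical(a$counts, b$counts)
  expect_identical(a$death_events_h, b$death_events_h)
  expect_identical(a$counters, b$counters)
  c <- simulate_run(cfg, 100)
  expect_false(identical(a$death_events_h, c$death_events_h) &&
               identical(a$counts, c$counts))
})

test_that("cells are conserved: census change equals births minus removals", {
  r <- simulate_run(eae_config(horizon_d = 15), 7)
  k <- r$counters
  nt <- dim(r$counts)[1]
  initial <- sum(r$counts[1, , ])
  final <- sum(r$counts[nt, , ])
  expect_equal(final, initial + k$births - k$removals)
  # migration alone never changes the census
  expect_gt(k$migrations, 0)
})

test_that("concentration fields stay nonnegative throughout a run", {
  set.seed(46)
  w <- eae_world(eae_config(horizon_d = 10))
  step_world(w, 1800)   # into the inflammatory phase
  for (f in c("type1_cytokine", "type2_cytokine", "demyelinating_agent")) {
    expect_true(all(world_field(w, "CNS", f) >= 0))
    expect_true(all(world_field(w, "SLO", f) >= 0))
  }
  r <- simulate_run(eae_config(horizon_d = 10), 8)
  expect_true(all(r$field_mass >= 0))
})

test_that("immunization DCs appear in the SLO per the linear schedule", {
  cfg <- eae_config(imm_dc_initial = 10, imm_dc_decrement = 2,
                    imm_dc_period_h = 6, horizon_d = 2)
  r <- simulate_run(cfg, 9)
  slo_dc <- r$counts[, "SLO", "DC"]
  i25 <- which.min(abs(r$t_h - 25))
  expect_equal(unname(slo_dc[i25]),
               sum(immunization_insertions(
                 immunization_schedule(10, 2, 6))$count))
})

test_that("the migration network declares valid endpoints and hazards", {
  net <- compartment_network(eae_config())
  comps <- compartment_names()
  expect_true(all(net$from %in% comps))
  expect_true(all(net$to %in% comps))
  expect_true(all(net$hazard_per_h >= 0))
  # every organ can reach the circulation and vice versa
  expect_setequal(unique(net$from[net$to == "CIRC"]),
                  setdiff(comps, "CIRC"))
})
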