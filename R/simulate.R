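#' Run one simulation to its horizon
#'
#' Creates a world from the configuration, steps it to the observation
#' horizon, and packages the recorded time series. Identical `(config, seed)`
#' pairs produce identical runs.
#'
#' @param config an [eae_config()].
#' @param seed integer seed for this run.
#' @return object of class `"eae_run"`: list with `t_h` (recording times),
#'   `counts` (array time x compartment x population), `field_mass` (array
#'   time x compartment x field), `death_events_h` (neuronal death times),
#'   `priming` (cumulative CD4Treg/CD8Treg primings per compartment),
#'   `counters` (instrumentation), `config`, `seed`.
#' @export
simulate_run <- function(config = eae_config(), seed = 1L) {
  set.seed(seed)
  raw <- cpp_world_run(engine_cfg(config))
  nt <- length(raw$t_h)
  counts <- array(raw$counts, dim = c(nt, 8L, 5L))       # row-major: pop fastest
  counts <- aperm(counts, c(1L, 3L, 2L))
  dimnames(counts) <- list(NULL, compartment_names(), population_names())
  mass <- array(raw$field_mass, dim = c(nt, 3L, 5L))
  mass <- aperm(mass, c(1L, 3L, 2L))
  dimnames(mass) <- list(NULL, compartment_names(),
                         c("type1_cytokine", "type2_cytokine",
                           "demyelinating_agent"))
  prim <- raw$priming
  dimnames(prim) <- list(c("CD4Treg", "CD8Treg"), compartment_names())
  structure(
    list(t_h = raw$t_h, counts = counts, field_mass = mass,
         death_events_h = raw$death_times_h, priming = prim,
         counters = raw$counters, config = config, seed = seed),
    class = "eae_run"
  )
}

#' @export
print.eae_run <- function(x, ...) {
  cat(sprintf("EAE simulation run (seed %d): %.0f h simulated, %d neuronal deaths\n",
              x$seed, max(x$t_h), length(x$death_events_h)))
  invisible(x)
}

#' Tidy per-run time series
#'
#' One row per recording time per compartment per population, the format the
#' runner writes to CSV.
#'
#' @param x an `eae_run`.
#' @param ... unused.
#' @return data frame with columns `run_id`, `t_hours`, `compartment`,
#'   `population`, `count`.
#' @export
as.data.frame.eae_run <- function(x, ...) {
  d <- expand.grid(t_hours = x$t_h, compartment = compartment_names(),
                   population = population_names(), stringsAsFactors = FALSE)
  d$count <- as.vector(x$counts)
  d$run_id <- x$seed
  d[, c("run_id", "t_hours", "compartment", "population", "count")]
}

#' Score a run's clinical course
#'
#' Smooths the run's neuronal-death events with the configured sliding window
#' and thresholds the rate into 0-5 EAE scores.
#'
#' @param run an `eae_run`.
#' @param rule a [scoring_rule()]; defaults to the rule embedded in the run's
#'   configuration.
#' @return a `clinical_course` (see [score_course()]).
#' @export
score_run <- function(run, rule = NULL) {
  cfg <- run$config
  if (is.null(rule))
    rule <- scoring_rule(cfg$score_window_h,
                         c(cfg$score_threshold_1, cfg$score_threshold_2,
                           cfg$score_threshold_3, cfg$score_threshold_4,
                           cfg$score_threshold_5))
  grid <- run$t_h[run$t_h > 0]
  rate <- smooth_rate(run$death_events_h, rule$window_h, grid)
  score_course(rate, rule, grid)
}

#' Clinical outcomes of one run
#'
#' @param run an `eae_run`.
#' @param rule optional [scoring_rule()] override.
#' @return the [extract_outcomes()] list for the run.
#' @export
run_outcomes <- function(run, rule = NULL) {
  cfg <- run$config
  extract_outcomes(score_run(run, rule),
                   remission_gap_h = cfg$remission_gap_h,
                   horizon_h = cfg$horizon_d * 24)
}

#' Run a seeded group of replicate simulations
#'
#' Executes `n` independent replicates with seeds derived from
#' `(master_seed, label, i)` and collects per-run clinical outcomes.
#'
#' @param config an [eae_config()].
#' @param n number of replicates.
#' @param master_seed integer master seed.
#' @param label experiment label entering seed derivation (paired-seed
#'   comparisons across groups share `master_seed` and replicate indices).
#' @param keep_runs also return the raw `eae_run` objects.
#' @return data frame of outcomes (one row per run: `run_id`, `seed`,
#'   `max_score`, `n_episodes`, `relapse_count`, `died`, `death_time_h`,
#'   `first_episode_duration_d`, `onset_d`, per-population peaks,
#'   `th1_at_40d`, `treg_primings`, `spleen_primings`), with the runs in
#'   `attr(, "runs")` if requested.
#' @export
run_group <- function(config = eae_config(), n = 100, master_seed = 1L,
                      label = "group", keep_runs = FALSE) {
  rows <- vector("list", n)
  runs <- if (keep_runs) vector("list", n) else NULL
  for (i in seq_len(n)) {
    run <- simulate_run(config, derive_seed(master_seed, label, i))
    oc <- run_outcomes(run)
    tot <- apply(run$counts, c(1, 3), sum)
    i40 <- which.min(abs(run$t_h - 960))
    rows[[i]] <- data.frame(
      run_id = i, seed = run$seed,
      max_score = oc$max_score, n_episodes = oc$n_episodes,
      relapse_count = oc$relapse_count, died = oc$died,
      death_time_h = oc$death_time_h,
      first_episode_duration_d = oc$first_episode_duration_d,
      onset_d = if (oc$n_episodes > 0) oc$episodes$onset_h[1] / 24 else NA_real_,
      peak_th1 = max(tot[, "CD4Th1"]), peak_th2 = max(tot[, "CD4Th2"]),
      peak_treg4 = max(tot[, "CD4Treg"]), peak_treg8 = max(tot[, "CD8Treg"]),
      th1_at_40d = unname(tot[i40, "CD4Th1"]),
      treg_primings = sum(run$priming),
      spleen_primings = sum(run$priming[, "SPLEEN"])
    )
    if (keep_runs) runs[[i]] <- run
  }
  out <- do.call(rbind, rows)
  if (keep_runs) attr(out, "runs") <- runs
  out
}

#' Robustness-analysis responses of one run
#'
#' The thirteen monitored responses: peak size and peak time (days) of the
#' four effector T-cell populations, the CD4Th1 count at 40 days, and the
#' maximum and 40-day EAE scores. For runs that die before day 40 the 40-day
#' responses carry the values at death (score 5).
#'
#' @param run an `eae_run`.
#' @return named list of 13 numeric responses.
#' @export
extract_responses <- function(run) {
  tot <- apply(run$counts, c(1, 3), sum)
  i40 <- which.min(abs(run$t_h - 960))
  resp <- list()
  for (p in c("CD4Th1", "CD4Th2", "CD4Treg", "CD8Treg")) {
    v <- tot[, p]
    resp[[paste0(p, "Max")]] <- max(v)
    resp[[paste0(p, "MaxTime")]] <- run$t_h[which.max(v)] / 24
  }
  resp$CD4Th1at40d <- tot[i40, "CD4Th1"]
  cs <- score_run(run)
  oc <- run_outcomes(run)
  resp$MaxEAE <- oc$max_score
  if (oc$died && oc$death_time_h <= 960) {
    resp$EAE40d <- 5
  } else {
    j <- which.min(abs(cs$t_h - 960))
    resp$EAE40d <- cs$score[j]
  }
  resp
}

#' Response distributions for a seeded group
#'
#' @inheritParams run_group
#' @return data frame, one row per run, columns = the 13 responses.
#' @export
run_group_responses <- function(config = eae_config(), n = 100,
                                master_seed = 1L, label = "sweep") {
  rows <- lapply(seq_len(n), function(i) {
    run <- simulate_run(config, derive_seed(master_seed, label, i))
    as.data.frame(extract_responses(run))
  })
  do.call(rbind, rows)
}
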