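#' Define a batch experiment
#'
#' An experiment is a named configuration (base config plus interventions)
#' run as a group of seeded replicates. Full experiments conventionally use
#' 500 replicates per group; reduced groups are legitimate for exploration.
#'
#' @param name experiment name (enters replicate seed derivation).
#' @param config an [eae_config()].
#' @param interventions optional [intervention_plan()] or list of plans.
#' @param n replicates.
#' @param horizon_d observation horizon in days (50 default; splenectomy
#'   immunization-strength grids conventionally use 200).
#' @return object of class `"experiment_spec"`.
#' @export
experiment_spec <- function(name, config = eae_config(),
                            interventions = NULL, n = 500, horizon_d = NULL) {
  stopifnot(n >= 1)
  if (!is.null(interventions)) config <- apply_intervention(config, interventions)
  if (!is.null(horizon_d)) config$horizon_d <- horizon_d
  validate_config(config)
  structure(list(name = name, config = config, n = n), class = "experiment_spec")
}

#' Run a batch experiment
#'
#' Executes the experiment's replicates with deterministically derived seeds
#' and writes (optionally) per-run outcome files, the group outcome table,
#' score series, and a manifest. Completed replicates found in `out_dir` are
#' not recomputed, so an interrupted batch resumes to identical final
#' outputs; outputs are keyed by replicate index, so execution order never
#' affects results.
#'
#' @param spec an [experiment_spec()].
#' @param master_seed integer master seed.
#' @param out_dir optional output directory.
#' @return outcomes data frame (see [run_group()]) with a `summary`
#'   attribute from [summarize_group()].
#' @export
run_experiment <- function(spec, master_seed = 1L, out_dir = NULL) {
  stopifnot(inherits(spec, "experiment_spec"))
  t_start <- Sys.time()
  rows <- vector("list", spec$n)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  for (i in seq_len(spec$n)) {
    f <- if (is.null(out_dir)) NULL else
      file.path(out_dir, sprintf("run_%04d_outcome.csv", i))
    if (!is.null(f) && file.exists(f)) {
      rows[[i]] <- utils::read.csv(f)
      next
    }
    run <- simulate_run(spec$config, derive_seed(master_seed, spec$name, i))
    oc <- run_outcomes(run)
    th1 <- rowSums(run$counts[, , "CD4Th1"])
    i40 <- which.min(abs(run$t_h - 960))
    row <- data.frame(
      run_id = i, seed = run$seed, max_score = oc$max_score,
      n_episodes = oc$n_episodes, relapse_count = oc$relapse_count,
      died = oc$died, death_time_h = oc$death_time_h,
      first_episode_duration_d = oc$first_episode_duration_d,
      onset_d = if (oc$n_episodes > 0) oc$episodes$onset_h[1] / 24 else NA_real_,
      peak_th1 = max(th1), th1_at_40d = th1[i40],
      treg_primings = sum(run$priming)
    )
    if (!is.null(f)) {
      tmp <- paste0(f, ".tmp")
      utils::write.csv(row, tmp, row.names = FALSE)
      file.rename(tmp, f)  # atomic publish
      cs <- score_run(run)
      utils::write.csv(
        data.frame(run_id = i, t_hours = cs$t_h, score = cs$score),
        file.path(out_dir, sprintf("run_%04d_scores.csv", i)),
        row.names = FALSE)
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    utils::write.csv(out, file.path(out_dir, "outcomes.csv"), row.names = FALSE)
    manifest <- list(experiment = spec$name, n = spec$n,
                     master_seed = master_seed,
                     config_hash = config_hash(spec$config),
                     termination = "completed",
                     wall_time_s = round(as.numeric(Sys.time() - t_start,
                                                    units = "secs"), 2),
                     written = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
    write_config_yaml(spec$config, file.path(out_dir, "config.yaml"))
  }
  attr(out, "summary") <- summarize_group(out)
  out
}

#' Experiment presets mirroring the published figure layouts
#'
#' Each preset is a list of [experiment_spec()]s: `"fig1"` control and
#' abrogated-regulation groups; `"fig2CD"` the regulatory-efficacy grid
#' (100, 60, 20, 5, 3, 2, 0 percent); `"fig2EF"` the Qa-1 duration grid
#' (0-24 h); `"fig3E"` control and splenectomy across immunization strengths
#' over 200 days; `"fig4"` / `"fig5"` the anti-CD3 efficacy grids
#' administered at day 4 / day 15.
#'
#' @param preset preset name.
#' @param n replicates per group.
#' @param config base configuration.
#' @return named list of `experiment_spec`s (first element = control group).
#' @export
figure_preset <- function(preset = c("fig1", "fig2CD", "fig2EF", "fig3E",
                                     "fig4", "fig5"),
                          n = 500, config = eae_config()) {
  preset <- match.arg(preset)
  sp <- function(name, plan = NULL, horizon = NULL, nn = n)
    experiment_spec(name, config, plan, nn, horizon)
  eff <- function(e) intervention_plan("regulatory_efficacy", e)
  qa1 <- function(h) intervention_plan("qa1_duration", h)
  acd3 <- function(e, d) intervention_plan("anti_cd3", e, d)
  switch(preset,
    fig1 = list(control = sp("fig1_control", nn = min(n, 5)),
                abrogated = sp("fig1_abrogated", eff(0), nn = min(n, 5))),
    fig2CD = {
      vals <- c(1, 0.6, 0.2, 0.05, 0.03, 0.02, 0)
      stats::setNames(
        lapply(vals, function(e) sp(sprintf("fig2_eff_%g", e), eff(e))),
        sprintf("efficacy_%g", vals))
    },
    fig2EF = {
      vals <- c(8, 24, 6, 3, 2, 1, 0)
      stats::setNames(
        lapply(vals, function(h) sp(sprintf("fig2_qa1_%g", h), qa1(h))),
        sprintf("qa1_%gh", vals))
    },
    fig3E = {
      periods <- c(6, 12, 24)
      specs <- list()
      for (p in periods) {
        cfgp <- config
        cfgp$imm_dc_period_h <- p
        specs[[sprintf("control_period_%gh", p)]] <-
          experiment_spec(sprintf("fig3_ctrl_p%g", p), cfgp, NULL, n, 200)
        specs[[sprintf("splenectomy_period_%gh", p)]] <-
          experiment_spec(sprintf("fig3_splx_p%g", p), cfgp,
                          intervention_plan("splenectomy"), n, 200)
      }
      specs
    },
    fig4 = {
      vals <- c(0, 0.4, 0.6, 0.7, 0.8, 0.9, 1)
      stats::setNames(
        lapply(vals, function(e) sp(sprintf("fig4_acd3_%g", e), acd3(e, 4))),
        sprintf("efficacy_%g", vals))
    },
    fig5 = {
      vals <- c(0, 0.7, 0.8, 0.9, 1)
      stats::setNames(
        lapply(vals, function(e) sp(sprintf("fig5_acd3_%g", e), acd3(e, 15))),
        sprintf("efficacy_%g", vals))
    })
}

#' Run a figure preset and summarize it
#'
#' Runs every group of a [figure_preset()] and emits the standard summary
#' bundle: per-group medians/IQRs and rates, max-score proportions, and
#' statistics (A-test bands, U and Fisher p-values) of every group against
#' the preset's control group.
#'
#' @param preset preset name (see [figure_preset()]).
#' @param n replicates per group.
#' @param master_seed integer master seed.
#' @param config base configuration.
#' @param out_dir optional directory for per-group outputs.
#' @return list with `outcomes` (named list of data frames), `summaries`,
#'   `max_score_props` (groups x scores 0..5), and `comparisons`
#'   (vs the first group).
#' @export
reproduce_figure <- function(preset, n = 100, master_seed = 1L,
                             config = eae_config(), out_dir = NULL) {
  specs <- figure_preset(preset, n, config)
  if (length(specs) == 0L) stop("empty preset grid")
  outcomes <- lapply(names(specs), function(nm) {
    dir <- if (is.null(out_dir)) NULL else file.path(out_dir, nm)
    run_experiment(specs[[nm]], master_seed, dir)
  })
  names(outcomes) <- names(specs)
  props <- t(vapply(outcomes, function(o)
    vapply(0:5, function(s) mean(o$max_score == s), numeric(1)),
    numeric(6)))
  colnames(props) <- as.character(0:5)
  comparisons <- lapply(outcomes[-1],
                        function(o) compare_groups(outcomes[[1]], o))
  list(outcomes = outcomes,
       summaries = lapply(outcomes, summarize_group),
       max_score_props = props,
       comparisons = comparisons)
}
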