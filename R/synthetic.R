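#' Synthetic neuronal-death-rate traces
#'
#' Generates Poisson death-event traces from parametric intensity profiles so
#' that the scoring and calibration layers can be exercised in isolation from
#' the simulator. Profiles emulate the canonical clinical courses: a
#' `"monophasic"` bump (onset, peak, resolution), a `"relapsing"` two-bump
#' course, or a `"fatal"` course with a high sustained peak. They reproduce
#' the timing of simulated disease, not its mechanism.
#'
#' @param n_runs number of traces.
#' @param pattern `"monophasic"`, `"relapsing"` or `"fatal"`.
#' @param peak_rate_per_h peak intensity, deaths/hour.
#' @param onset_d,peak_d,end_d shape landmarks in days.
#' @param relapse_gap_d gap between bumps for the relapsing pattern.
#' @param horizon_d observation horizon in days.
#' @return list of numeric vectors of death times in hours.
#' @export
synth_death_events <- function(n_runs = 10,
                               pattern = c("monophasic", "relapsing", "fatal"),
                               peak_rate_per_h = 2, onset_d = 10, peak_d = 15,
                               end_d = 23, relapse_gap_d = 10, horizon_d = 50) {
  pattern <- match.arg(pattern)
  bump <- function(t_h, a_d, p_d, b_d, height) {
    # piecewise-linear tent in days, evaluated on an hourly grid
    t_d <- t_h / 24
    up <- pmax(0, pmin(1, (t_d - a_d) / max(p_d - a_d, 1e-9)))
    dn <- pmax(0, pmin(1, (b_d - t_d) / max(b_d - p_d, 1e-9)))
    height * pmin(up, dn)
  }
  grid <- seq(0, horizon_d * 24, by = 1)
  lambda <- switch(pattern,
    monophasic = bump(grid, onset_d, peak_d, end_d, peak_rate_per_h),
    fatal = bump(grid, onset_d, peak_d, end_d, 2.5 * peak_rate_per_h),
    relapsing = bump(grid, onset_d, peak_d, end_d, peak_rate_per_h) +
      bump(grid, end_d + relapse_gap_d,
           end_d + relapse_gap_d + (peak_d - onset_d),
           end_d + relapse_gap_d + (end_d - onset_d),
           0.7 * peak_rate_per_h)
  )
  lapply(seq_len(n_runs), function(i) {
    counts <- stats::rpois(length(lambda), lambda)
    rep(grid, counts) + stats::runif(sum(counts))
  })
}

#' Synthetic two-sample datasets for the statistics layer
#'
#' Draws paired samples from shifted discrete or continuous distributions,
#' with controllable tie density, for testing rank-based statistics.
#'
#' @param n,m sample sizes.
#' @param shift location shift of the second sample.
#' @param discrete if `TRUE`, Poisson samples (heavy ties); else normal.
#' @return list with elements `x` and `y`.
#' @export
synth_two_samples <- function(n = 50, m = 50, shift = 0, discrete = TRUE) {
  if (discrete) {
    list(x = stats::rpois(n, 3), y = stats::rpois(m, 3 + shift))
  } else {
    list(x = stats::rnorm(n), y = stats::rnorm(m, shift))
  }
}
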