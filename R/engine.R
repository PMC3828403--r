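#' @useDynLib eaesim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Compartment and population names
#'
#' Index order used throughout the engine's outputs.
#' @return character vector.
#' @export
compartment_names <- function() c("CNS", "CLN", "CIRC", "SPLEEN", "SLO")

#' @rdname compartment_names
#' @export
population_names <- function() {
  c("Neuron", "Microglia", "DC", "CD4Th", "CD4Th1", "CD4Th2",
    "CD4Treg", "CD8Treg")
}

#' The inter-compartment migration network
#'
#' Directed migration routes with per-cell-class hazards, assembled from the
#' configuration: every organ exits to the circulation, the circulation feeds
#' the lymphoid organs (and, for effector T cells only, the CNS), and
#' antigen-bearing CNS dendritic cells drain directly to the cervical lymph
#' node. Editing the hazard parameters in the config edits the network.
#'
#' @param cfg an [eae_config()].
#' @return data frame with columns `from`, `to`, `cell_class`, `hazard_per_h`.
#' @export
compartment_network <- function(cfg = eae_config()) {
  organs <- c("CNS", "CLN", "SPLEEN", "SLO")
  rbind(
    data.frame(from = organs, to = "CIRC", cell_class = "naive_t",
               hazard_per_h = cfg$naive_exit_per_h),
    data.frame(from = organs, to = "CIRC", cell_class = "effector_t",
               hazard_per_h = cfg$effector_exit_per_h),
    data.frame(from = "CIRC", to = c("SPLEEN", "CLN", "SLO"),
               cell_class = "any_t",
               hazard_per_h = c(cfg$circ_to_spleen_per_h,
                                cfg$circ_to_cln_per_h, cfg$circ_to_slo_per_h)),
    data.frame(from = "CIRC", to = "CNS", cell_class = "effector_th",
               hazard_per_h = cfg$effector_cns_entry_per_h),
    data.frame(from = "CIRC", to = "CNS", cell_class = "effector_treg",
               hazard_per_h = cfg$treg_cns_entry_per_h),
    data.frame(from = "CNS", to = "CLN", cell_class = "antigen_dc",
               hazard_per_h = cfg$cns_dc_migration_per_h)
  )
}

# full engine configuration: registry parameters plus the expanded
# immunization schedule (single source of truth: the R closed form)
engine_cfg <- function(cfg) {
  validate_config(cfg)
  ins <- immunization_insertions(
    immunization_schedule(cfg$imm_dc_initial, cfg$imm_dc_decrement,
                          cfg$imm_dc_period_h),
    horizon_h = cfg$horizon_d * 24
  )
  c(unclass(cfg),
    list(imm_insertion_t_h = ins$t_h, imm_insertion_count = ins$count))
}

#' Create a simulation world
#'
#' Builds the initial state: resident neurons, microglia and dendritic cells,
#' naive T-cell repertoires, empty cytokine fields. All randomness comes from
#' R's RNG; call `set.seed()` first for a reproducible run.
#'
#' @param cfg an [eae_config()].
#' @return opaque world handle of class `"eae_world"`.
#' @seealso [step_world()], [world_state()], [simulate_run()].
#' @export
eae_world <- function(cfg = eae_config()) {
  structure(list(ptr = cpp_world_create(engine_cfg(cfg)), config = cfg),
            class = "eae_world")
}

#' Advance a world by n steps
#'
#' Each step advances the clock by `dt_min` simulated minutes through the
#' fixed phase order (immunization insertions, recruitment, timers, binding,
#' movement, migration, fields, neuronal death check, recording). Stepping a
#' run past its horizon signals a terminal-state error.
#'
#' @param world an [eae_world()].
#' @param n number of steps.
#' @return `world`, invisibly.
#' @export
step_world <- function(world, n = 1L) {
  stopifnot(inherits(world, "eae_world"))
  cpp_world_step(world$ptr, as.integer(n))
  invisible(world)
}

#' Inspect world state
#'
#' `world_state` returns the clock; `world_cells` a data frame of all live
#' cells (population, state, compartment, coordinates, receptor flags);
#' `world_field` one concentration grid.
#'
#' @param world an [eae_world()].
#' @return see above.
#' @export
world_state <- function(world) {
  st <- cpp_world_time(world$ptr)
  st$t <- st$t_h  # elapsed simulated hours
  st
}

#' @rdname world_state
#' @export
world_cells <- function(world) {
  d <- cpp_world_cells(world$ptr)
  d$population <- population_names()[d$pop + 1L]
  d$compartment <- compartment_names()[d$comp + 1L]
  d
}

#' @rdname world_state
#' @param compartment compartment name (see [compartment_names()]).
#' @param field one of `"type1_cytokine"`, `"type2_cytokine"`,
#'   `"demyelinating_agent"`.
#' @export
world_field <- function(world, compartment = "CNS",
                        field = "demyelinating_agent") {
  ci <- match(compartment, compartment_names()) - 1L
  fi <- match(field, c("type1_cytokine", "type2_cytokine",
                       "demyelinating_agent")) - 1L
  if (is.na(ci) || is.na(fi)) stop("unknown compartment or field")
  cpp_world_field(world$ptr, ci, fi)
}

#' Diffuse and decay a concentration field
#'
#' One explicit forward-Euler step of the 4-neighbour Laplacian with
#' exponential decay applied first. Boundaries are closed (no-flux) walls, or
#' toroidal wrap when `toroidal = TRUE`; with zero decay, total mass is
#' conserved under both. Stability requires `D * dt <= 0.25` (grid spacing 1).
#'
#' @param field nonnegative numeric matrix.
#' @param D diffusion coefficient, grid^2 per hour.
#' @param lambda decay rate per hour (>= 0).
#' @param dt time step in hours.
#' @param toroidal wrap boundaries instead of closed walls.
#' @return matrix of the same shape.
#' @export
diffuse_decay <- function(field, D, lambda, dt, toroidal = FALSE) {
  cpp_diffuse_decay(field, D, lambda, dt, toroidal)
}

#' Draw state-transition durations
#'
#' Durations are drawn from a normal distribution with the given mean and
#' standard deviation and clamped at zero (clamping, not redrawing, so the
#' draw count per RNG stream is deterministic).
#'
#' @param n number of draws.
#' @param mean_h,sd_h distribution parameters in hours (`sd_h >= 0`).
#' @return numeric vector of nonnegative durations.
#' @export
draw_duration <- function(n, mean_h, sd_h) cpp_draw_duration(n, mean_h, sd_h)

#' Attempt a probabilistic receptor binding
#'
#' A binding succeeds with probability `p` times the product of all
#' multiplicative modifiers (e.g. the anti-CD3 factor `1 - efficacy`). The
#' product must lie in \[0, 1\].
#'
#' @param n number of independent attempts.
#' @param p base success probability of the binding rule.
#' @param modifiers numeric vector of multiplicative probability factors.
#' @return logical vector.
#' @export
attempt_binding <- function(n, p, modifiers = numeric(0)) {
  cpp_attempt_binding(n, p, modifiers)
}

#' One CD8Treg kill attempt on a bound CD4Th1 target
#'
#' Given an established TCR:Qa-1 binding with a CD4Th1 whose Qa-1:TCR-peptide
#' window is still open, the CD8Treg apoptoses the target with probability
#' `regulatory_efficacy`. Calling this on a target whose Qa-1 window has
#' expired is a contract violation.
#'
#' @param n number of independent bound encounters.
#' @param efficacy regulatory efficacy in \[0, 1\].
#' @param qa1_active is the target's Qa-1 timer still running?
#' @return logical vector: was the target killed?
#' @export
cd8treg_kill_attempt <- function(n, efficacy, qa1_active = TRUE) {
  if (!isTRUE(qa1_active))
    stop("kill attempt on a target no longer expressing Qa-1:TCR-peptide")
  if (efficacy < 0 || efficacy > 1) stop("efficacy must be in [0, 1]")
  stats::runif(n) < efficacy
}

#' One unbiased random-walk move on a lattice
#'
#' Uniform draw over the 8 Moore neighbours; closed walls reject the move
#' (the cell stays), toroidal boundaries wrap.
#'
#' @param x,y current coordinate (0-based).
#' @param w,h grid dimensions.
#' @param toroidal wrap instead of walls.
#' @return integer vector `c(x, y)` of the new coordinate.
#' @export
random_walk_step <- function(x, y, w, h, toroidal = FALSE) {
  cpp_random_walk_step(x, y, w, h, toroidal)
}
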