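#' Parameter registry for the simulator
#'
#' Every tunable simulation parameter with its default calibrated value, unit
#' and legal range. The defaults constitute the package's calibrated control
#' configuration; the robustness analysis iterates over this registry.
#' Probabilistic interaction parameters are expressed as hazard rates per
#' hour (converted internally to per-step probabilities `1 - exp(-rate*dt)`),
#' so their values do not depend on the step size.
#'
#' @return data frame with columns `name`, `default`, `unit`, `lower`,
#'   `upper`, `description`.
#' @export
config_registry <- function() {
  p <- function(name, default, unit, lower, upper, description)
    data.frame(name = name, default = default, unit = unit, lower = lower,
               upper = upper, description = description)
  rbind(
    ## -- engine / space-time ------------------------------------------------
    p("dt_min", 6, "min", 0.5, 60, "simulated minutes per step"),
    p("horizon_d", 50, "d", 1, 400, "observation horizon"),
    p("record_interval_h", 1, "h", 0.1, 24, "recording interval"),
    p("cns_grid", 20, "cells", 4, 200, "CNS lattice side length"),
    p("cln_grid", 12, "cells", 4, 200, "cervical lymph node lattice side"),
    p("circ_grid", 20, "cells", 4, 200, "circulation lattice side"),
    p("spleen_grid", 16, "cells", 4, 200, "spleen lattice side"),
    p("slo_grid", 12, "cells", 4, 200, "secondary lymphoid organ lattice side"),
    p("toroidal_circulation", 1, "flag", 0, 1, "toroidal wrap for circulation"),
    p("cell_motility", 1, "prob/step", 0, 1, "probability a motile cell moves"),
    ## -- cytokine and soluble-factor fields --------------------------------
    p("cytokine_diffusion_grid2_h", 0.5, "grid^2/h", 0, 2.4,
      "diffusion coefficient, type-1/type-2 cytokines"),
    p("demyel_diffusion_grid2_h", 0.3, "grid^2/h", 0, 2.4,
      "diffusion coefficient, demyelinating agent"),
    p("type1_decay_per_h", 0.3, "1/h", 0, 20, "type-1 cytokine decay rate"),
    p("type2_decay_per_h", 0.3, "1/h", 0, 20, "type-2 cytokine decay rate"),
    p("demyel_decay_per_h", 1, "1/h", 0, 20, "demyelinating agent decay rate"),
    ## -- immunization -------------------------------------------------------
    p("imm_dc_initial", 8, "cells", 0, 1000, "immunization DCs at induction"),
    p("imm_dc_decrement", 1, "cells", 0, 1000, "linear decrement per insertion"),
    p("imm_dc_period_h", 6, "h", 0.5, 96, "hours between insertions (6 = control)"),
    p("dc_lifespan_mean_h", 300, "h", 1, 2000, "dendritic cell lifespan mean"),
    p("dc_lifespan_sd_h", 60, "h", 0, 500, "dendritic cell lifespan sd"),
    ## -- resident CNS populations ------------------------------------------
    p("n_neurons", 450, "cells", 1, 5000, "neurons resident in the CNS"),
    p("neuron_kill_threshold", 1.0, "conc", 0.01, 100,
      "local demyelinating-agent concentration killing a neuron"),
    p("neuron_kill_per_h", 0.3, "1/h", 0, 50,
      "neuron death hazard while the local concentration is lethal"),
    p("neuron_replace_delay_h", 24, "h", 0, 2000, "neuron replacement delay"),
    p("n_microglia", 200, "cells", 0, 5000, "microglia resident in the CNS"),
    p("microglia_active_h", 10, "h", 0.1, 500, "microglia activation duration"),
    p("demyel_secretion_per_h", 1, "conc/h", 0, 100,
      "demyelinating-agent secretion by activated microglia"),
    p("n_cns_dc", 5, "cells", 0, 500, "resident CNS dendritic cells"),
    p("antigen_dc_lifespan_h", 50, "h", 1, 2000,
      "lifespan of antigen-bearing (myelin-presenting) CNS dendritic cells"),
    p("cns_dc_migration_per_h", 0.16, "1/h", 0, 20,
      "antigen-bearing CNS DC emigration hazard to the CLN"),
    p("cns_dc_replace_delay_h", 24, "h", 0, 2000, "CNS DC replacement delay"),
    p("n_splenic_dc", 25, "cells", 0, 500, "resident splenic dendritic cells"),
    p("n_cln_dc", 8, "cells", 0, 500, "resident CLN dendritic cells"),
    ## -- naive repertoires --------------------------------------------------
    p("th_naive_target", 30, "cells", 0, 2000,
      "naive CD4Th homeostatic target per lymphoid organ"),
    p("treg4_naive_target", 10, "cells", 0, 2000,
      "naive CD4Treg target per lymphoid organ"),
    p("treg8_naive_target", 10, "cells", 0, 2000,
      "naive CD8Treg target per lymphoid organ"),
    p("recruit_per_h", 0.5, "cells/h", 0, 100, "naive recruitment refill rate"),
    ## -- T cell activation, proliferation and death -------------------------
    p("th_prime_per_h", 0.012, "1/h", 0, 50,
      "CD4Th priming hazard per adjacent MBP-presenting DC"),
    p("division_interval_h", 24, "h", 0.5, 200, "time between cell divisions"),
    p("th_divisions", 4, "divisions", 0, 10, "CD4Th proliferative divisions"),
    p("treg4_divisions", 1, "divisions", 0, 10, "CD4Treg divisions"),
    p("treg8_divisions", 2, "divisions", 0, 10, "CD8Treg divisions"),
    p("tcell_aicd_mean_h", 90, "h", 1, 2000,
      "mean effector T cell lifespan before activation-induced cell death"),
    p("tcell_aicd_sd_h", 34, "h", 0, 500, "sd of effector T cell lifespan"),
    p("apoptotic_removal_h", 24, "h", 0.1, 500,
      "persistence of apoptotic cells before removal"),
    ## -- regulatory circuit -------------------------------------------------
    p("qa1_duration_mean_h", 8, "h", 0, 24, "mean Qa-1:TCR-peptide expression"),
    p("qa1_duration_sd_h", 1, "h", 0, 24, "sd of Qa-1 expression duration"),
    p("qa1_bind_per_h", 6, "1/h", 0, 50,
      "CD8Treg TCR:Qa-1 binding hazard per adjacent Qa-1+ CD4Th1"),
    p("regulatory_efficacy", 1, "prob", 0, 1,
      "probability a bound CD8Treg apoptoses its CD4Th1 target"),
    p("treg4_prime_per_h", 0.3, "1/h", 0, 50,
      "CD4Treg priming hazard per adjacent TCR-peptide-presenting DC"),
    p("treg8_prime_per_h", 0.3, "1/h", 0, 50,
      "CD8Treg priming hazard per adjacent licensed presenting DC"),
    p("license_per_h", 2, "1/h", 0, 50,
      "DC licensing hazard per adjacent effector CD4Treg"),
    p("phagocytosis_per_h", 2, "1/h", 0, 50,
      "DC phagocytosis hazard per adjacent apoptotic T cell"),
    p("th1_microglia_bind_per_h", 1, "1/h", 0, 50,
      "CD4Th1 TCR:MHC binding hazard per adjacent microglia"),
    ## -- cytokines and polarization -----------------------------------------
    p("polarization_ratio_threshold", 1, "ratio", 0.01, 100,
      "type1:type2 ratio above which a priming CD4Th polarizes to Th1"),
    p("type1_secretion_per_h", 1, "conc/h", 0, 100, "Th1 type-1 secretion"),
    p("type2_secretion_per_h", 1, "conc/h", 0, 100, "Th2 type-2 secretion"),
    p("dc_type1_secretion_per_h", 1, "conc/h", 0, 100,
      "type-1 secretion by type-1 polarized immunization DCs"),
    p("basal_type2_per_h", 0.1, "conc/h", 0, 10,
      "basal type-2 secretion per lymphoid grid-space"),
    p("demyel_source_direct", 0, "flag", 0, 1,
      "1: CD4Th1 secrete demyelinating agent directly; 0: via microglia"),
    ## -- migration ----------------------------------------------------------
    p("naive_exit_per_h", 0.1, "1/h", 0, 20, "naive T cell organ exit hazard"),
    p("effector_exit_per_h", 0.2, "1/h", 0, 20,
      "effector T cell organ exit hazard"),
    p("circ_to_spleen_per_h", 0.4, "1/h", 0, 20,
      "circulation-to-spleen entry hazard"),
    p("circ_to_cln_per_h", 0.1, "1/h", 0, 20, "circulation-to-CLN entry hazard"),
    p("circ_to_slo_per_h", 0.1, "1/h", 0, 20, "circulation-to-SLO entry hazard"),
    p("effector_cns_entry_per_h", 0.045, "1/h", 0, 20,
      "effector Th1/Th2 circulation-to-CNS entry hazard"),
    p("treg_cns_entry_per_h", 0.05, "1/h", 0, 20,
      "effector Treg circulation-to-CNS entry hazard"),
    p("treg_lymphoid_entry_factor", 0.05, "fraction", 0, 1,
      "lymph-node entry of effector Tregs relative to other T cells"),
    p("bbb_base_frac", 1, "fraction", 0, 1,
      "blood-brain-barrier permeability of the uninflamed CNS"),
    p("bbb_halfmax_microglia", 20, "cells", 0.1, 10000,
      "activated-microglia count at half-maximal barrier permeability"),
    ## -- interventions ------------------------------------------------------
    p("splenectomy", 0, "flag", 0, 1,
      "1: spleen replaced pre-induction by a zero-capacity pass-through"),
    p("anti_cd3_efficacy", 0, "prob", 0, 1,
      "anti-CD3 efficacy; TCR binding probabilities are multiplied by 1-e"),
    p("anti_cd3_admin_d", -1, "d", -1, 400,
      "anti-CD3 administration day post-induction (-1 = never)"),
    p("anti_cd3_blocks_qa1", 1, "flag", 0, 1,
      "anti-CD3 also blocks CD8Treg TCR:Qa-1 recognition"),
    ## -- clinical scoring ---------------------------------------------------
    p("score_window_h", 48, "h", 1, 200, "sliding-window width for scoring"),
    p("score_threshold_1", 0.333, "deaths/h", 0.001, 100, "score-1 rate cutoff"),
    p("score_threshold_2", 0.600, "deaths/h", 0.001, 100, "score-2 rate cutoff"),
    p("score_threshold_3", 0.867, "deaths/h", 0.001, 100, "score-3 rate cutoff"),
    p("score_threshold_4", 1.133, "deaths/h", 0.001, 100, "score-4 rate cutoff"),
    p("score_threshold_5", 1.460, "deaths/h", 0.001, 100,
      "score-5 (death) rate cutoff"),
    p("remission_gap_h", 24, "h", 0, 500,
      "minimum score-0 gap separating clinical episodes")
  )
}

#' Build a simulation configuration
#'
#' Returns the full default calibrated configuration, with any named
#' overrides applied and validated against the registry's legal ranges.
#'
#' @param ... named parameter overrides (see [config_registry()]).
#' @return named list of class `"eae_config"`.
#' @examples
#' cfg <- eae_config(regulatory_efficacy = 0.05)
#' @export
eae_config <- function(...) {
  reg <- config_registry()
  cfg <- as.list(stats::setNames(reg$default, reg$name))
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), reg$name)
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- lapply(dots, as.numeric)
  }
  cfg <- structure(cfg, class = "eae_config")
  validate_config(cfg)
  cfg
}

#' Validate a configuration against the registry
#'
#' Checks that every registry parameter is present, numeric, finite and
#' within its legal range, and that the scoring thresholds ascend.
#'
#' @param cfg an `eae_config` (or plain named list).
#' @return `cfg`, invisibly; signals an error describing every violation.
#' @export
validate_config <- function(cfg) {
  reg <- config_registry()
  missing <- setdiff(reg$name, names(cfg))
  if (length(missing))
    stop("configuration is missing parameter(s): ",
         paste(missing, collapse = ", "))
  probs <- character(0)
  for (i in seq_len(nrow(reg))) {
    v <- cfg[[reg$name[i]]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      probs <- c(probs, sprintf("%s: not a finite number", reg$name[i]))
    } else if (v < reg$lower[i] || v > reg$upper[i]) {
      probs <- c(probs, sprintf("%s = %g outside legal range [%g, %g]",
                                reg$name[i], v, reg$lower[i], reg$upper[i]))
    }
  }
  th <- vapply(paste0("score_threshold_", 1:5), function(n)
    as.numeric(cfg[[n]]), numeric(1))
  if (any(diff(th) <= 0))
    probs <- c(probs, "score thresholds must be strictly ascending")
  dth <- cfg$dt_min / 60
  for (Dn in c("cytokine_diffusion_grid2_h", "demyel_diffusion_grid2_h")) {
    if (is.numeric(cfg[[Dn]]) && cfg[[Dn]] * dth > 0.25)
      probs <- c(probs, sprintf(
        "%s = %g violates the forward-Euler stability bound D*dt <= 0.25",
        Dn, cfg[[Dn]]))
  }
  if (length(probs))
    stop("invalid configuration:\n  ", paste(probs, collapse = "\n  "))
  invisible(cfg)
}

#' Legal range of a registry parameter
#'
#' @param name parameter name.
#' @return numeric length-2 vector `c(lower, upper)`.
#' @export
config_legal_range <- function(name) {
  reg <- config_registry()
  i <- match(name, reg$name)
  if (is.na(i)) stop("unknown parameter: ", name)
  c(reg$lower[i], reg$upper[i])
}

#' Read / write configurations as YAML
#'
#' Plain key/value YAML holding every registry parameter by canonical name.
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path file path.
#' @return [read_config_yaml()] returns an `eae_config`;
#'   [write_config_yaml()] returns `path` invisibly.
#' @export
read_config_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(eae_config, vals)
}

#' @rdname read_config_yaml
#' @param cfg an `eae_config`.
#' @export
write_config_yaml <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' 32-bit FNV-1a over the canonical `name=value` serialization; used for run
#' manifests and sweep provenance.
#'
#' @param cfg an `eae_config`.
#' @return character scalar, 8 hex digits.
#' @export
config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v) sprintf("%.12g", v), ""),
             sep = "=", collapse = ";")
  fnv1a32(s)
}

# 32-bit FNV-1a of a string, returned as hex. Used for hashing and seed
# derivation; implemented with plain doubles (exact below 2^53).
fnv1a32 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor_dbl(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  # h may exceed .Machine$integer.max; format as two 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

bitwXor_dbl <- function(a, b) {
  # bitwXor on doubles that may exceed .Machine$integer.max
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi <- bitwXor((a %/% 65536) %% 65536, (b %/% 65536) %% 65536)
  hi * 65536 + lo
}

#' Derive a replicate seed from a master seed
#'
#' Deterministic hash of `(master_seed, label, index)` into `[1, 2^31 - 2]`.
#' Guarantees that replicate i of one experiment is paired with replicate i
#' of another experiment run from the same master seed, supporting
#' variance-reduced paired-seed comparisons.
#'
#' @param master_seed integer master seed.
#' @param label character experiment label.
#' @param index replicate index (default 0).
#' @return integer seed.
#' @export
derive_seed <- function(master_seed, label = "run", index = 0L) {
  h <- fnv1a32(paste(master_seed, label, index, sep = "/"))
  as.integer(strtoi(substr(h, 1, 7), 16L) %% 2147483646L + 1L)
}
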