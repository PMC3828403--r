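#' In-silico intervention plans
#'
#' The four interventions are declarative transforms of a configuration:
#' \describe{
#'   \item{regulatory_efficacy}{sets the probability that a bound CD8Treg
#'     apoptoses its CD4Th1 target (1 = control, 0 = complete absence of
#'     regulation).}
#'   \item{qa1_duration}{sets the mean of the Qa-1:TCR-peptide expression
#'     window (hours, 0-24; control 8 h, sd stays 1 h).}
#'   \item{splenectomy}{replaces the spleen, before induction, by a
#'     zero-capacity pass-through compartment without splenic DCs.}
#'   \item{anti_cd3}{from the administration day onward multiplies every
#'     T-cell TCR binding probability by `1 - value` (value = efficacy;
#'     0 = control, 1 blocks all TCR bindings). Affects all T cells,
#'     including Tregs.}
#' }
#'
#' @param kind one of `"regulatory_efficacy"`, `"qa1_duration"`,
#'   `"splenectomy"`, `"anti_cd3"`.
#' @param value kind-specific: probability, mean hours, ignored, or efficacy.
#' @param admin_time_d administration day post-induction. Only anti-CD3 uses
#'   a positive time (conventionally day 4, onset of encephalitogenic
#'   expansion, or day 15, peak clinical disease); splenectomy must be at or
#'   before induction.
#' @return object of class `"intervention_plan"`.
#' @export
intervention_plan <- function(kind = c("regulatory_efficacy", "qa1_duration",
                                       "splenectomy", "anti_cd3"),
                              value = NULL, admin_time_d = 0) {
  kind <- match.arg(kind)
  switch(kind,
    regulatory_efficacy = {
      if (!is.numeric(value) || value < 0 || value > 1)
        stop("regulatory efficacy must be a probability in [0, 1]")
    },
    qa1_duration = {
      if (!is.numeric(value) || value < 0 || value > 24)
        stop("Qa-1 mean duration must be in [0, 24] hours")
    },
    splenectomy = {
      if (admin_time_d > 0)
        stop("splenectomy must be performed before induction (admin_time_d <= 0)")
      value <- NA_real_
    },
    anti_cd3 = {
      if (!is.numeric(value) || value < 0 || value > 1)
        stop("anti-CD3 efficacy must be in [0, 1]")
      if (admin_time_d < 0) stop("anti-CD3 administration day must be >= 0")
    }
  )
  structure(list(kind = kind, value = value, admin_time_d = admin_time_d),
            class = "intervention_plan")
}

#' Apply an intervention plan to a configuration
#'
#' Each plan touches only its declared parameters; everything else in the
#' configuration is unchanged.
#'
#' @param config an [eae_config()].
#' @param plan an [intervention_plan()] (or a list of plans, applied in
#'   order).
#' @return the modified configuration.
#' @export
apply_intervention <- function(config, plan) {
  if (is.list(plan) && !inherits(plan, "intervention_plan")) {
    for (p in plan) config <- apply_intervention(config, p)
    return(config)
  }
  stopifnot(inherits(plan, "intervention_plan"))
  switch(plan$kind,
    regulatory_efficacy = { config$regulatory_efficacy <- plan$value },
    qa1_duration = { config$qa1_duration_mean_h <- plan$value },
    splenectomy = { config$splenectomy <- 1 },
    anti_cd3 = {
      config$anti_cd3_efficacy <- plan$value
      config$anti_cd3_admin_d <- plan$admin_time_d
    }
  )
  validate_config(config)
  config
}

#' @rdname apply_intervention
#' @param p regulatory efficacy in \[0, 1\].
#' @export
apply_regulatory_efficacy <- function(config, p)
  apply_intervention(config, intervention_plan("regulatory_efficacy", p))

#' @rdname apply_intervention
#' @param mean_h Qa-1 mean expression duration in hours.
#' @export
apply_qa1_duration <- function(config, mean_h)
  apply_intervention(config, intervention_plan("qa1_duration", mean_h))

#' @rdname apply_intervention
#' @export
apply_splenectomy <- function(config)
  apply_intervention(config, intervention_plan("splenectomy"))

#' @rdname apply_intervention
#' @param efficacy anti-CD3 efficacy in \[0, 1\].
#' @param admin_day administration day post-induction.
#' @export
apply_anti_cd3 <- function(config, efficacy, admin_day = 4)
  apply_intervention(config,
                     intervention_plan("anti_cd3", efficacy, admin_day))
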