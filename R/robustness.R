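#' Does a perturbed response distribution deviate significantly from control?
#'
#' A significant deviation is a large A-test effect versus the control
#' distribution or, for EAE-score responses, an absolute difference in mean
#' score of at least 1.0. The two rules are independent: either alone
#' triggers a deviation.
#'
#' @param x numeric vector of per-run response values at the perturbed value.
#' @param control numeric vector of per-run control response values.
#' @param eae_response if `TRUE`, additionally apply the mean +/- 1.0 rule.
#' @param eae_delta threshold for the EAE mean rule (score points).
#' @return logical.
#' @export
response_deviation <- function(x, control, eae_response = FALSE,
                               eae_delta = 1.0) {
  if (length(x) == 0L || length(control) == 0L) return(NA)
  big <- classify_effect(a_test(x, control)$A) == "large"
  if (eae_response)
    big <- big || abs(mean(x) - mean(control)) >= eae_delta
  big
}

#' Locate significant-deviation boundaries along a parameter sweep
#'
#' Walks outward from the default value along the sorted sweep: the lower
#' boundary LB is the first swept value below the default at which a
#' significant deviation holds, the upper boundary UB the first above. `NaN`
#' is assigned where no swept value on that side deviates.
#'
#' @param values numeric vector of swept parameter values (must contain
#'   `default`).
#' @param default the default (calibrated) parameter value.
#' @param deviates logical vector parallel to `values`: does the response at
#'   that value deviate significantly from control?
#' @return list with `LB` and `UB` (numeric, possibly `NaN`).
#' @export
find_boundaries <- function(values, default, deviates) {
  stopifnot(length(values) == length(deviates))
  if (!any(values == default))
    stop("the sweep must include the default value")
  o <- order(values)
  values <- values[o]
  deviates <- deviates[o]
  below <- rev(which(values < default))  # walking down from the default
  above <- which(values > default)      # walking up
  first_dev <- function(idx) {
    for (i in idx) if (isTRUE(deviates[i])) return(values[i])
    NaN
  }
  list(LB = first_dev(below), UB = first_dev(above))
}

#' Robustness indices from deviation boundaries
#'
#' The lower/upper index is the distance between the boundary and the default
#' expressed as a percentage of the default; the robustness index RI is the
#' smaller of the two over non-NaN indices (NaN if both are NaN). For
#' parameters whose default is zero the percentage is undefined: indices are
#' NaN and the absolute distances are reported instead.
#'
#' @param LB,UB boundaries from [find_boundaries()] (may be `NaN`).
#' @param default default parameter value.
#' @return list with `LI`, `UI`, `RI`, and (zero-default case only)
#'   `abs_lower`/`abs_upper`.
#' @export
robustness_index <- function(LB, UB, default) {
  if (default == 0) {
    return(list(LI = NaN, UI = NaN, RI = NaN,
                abs_lower = abs(default - LB), abs_upper = abs(UB - default)))
  }
  LI <- abs(default - LB) / abs(default) * 100
  UI <- abs(UB - default) / abs(default) * 100
  pool <- c(LI, UI)
  RI <- if (all(is.nan(pool))) NaN else min(pool, na.rm = TRUE)
  list(LI = LI, UI = UI, RI = RI)
}

#' Per-parameter robustness record over all monitored responses
#'
#' For one swept parameter, compares the response distributions at every
#' swept value against the control (default-value) distributions and reports,
#' per response, the deviation boundaries and indices.
#'
#' @param responses_by_value named list, one element per swept value (names
#'   are the values), each a data frame of per-run responses (columns =
#'   response names).
#' @param values numeric vector of swept values, parallel to
#'   `responses_by_value`.
#' @param default default parameter value (must be among `values`).
#' @param eae_responses response columns subject to the mean +/- 1.0 rule.
#' @return data frame with columns `response`, `LB`, `UB`, `LI`, `UI`, `RI`.
#' @export
parameter_robustness <- function(responses_by_value, values, default,
                                 eae_responses = c("MaxEAE", "EAE40d")) {
  stopifnot(length(responses_by_value) == length(values))
  control <- responses_by_value[[which(values == default)[1L]]]
  resp_names <- names(control)
  recs <- lapply(resp_names, function(rn) {
    dev <- vapply(seq_along(values), function(i) {
      if (values[i] == default) return(FALSE)
      isTRUE(response_deviation(responses_by_value[[i]][[rn]], control[[rn]],
                                eae_response = rn %in% eae_responses))
    }, logical(1))
    b <- find_boundaries(values, default, dev)
    idx <- robustness_index(b$LB, b$UB, default)
    data.frame(response = rn, LB = b$LB, UB = b$UB,
               LI = idx$LI, UI = idx$UI, RI = idx$RI)
  })
  do.call(rbind, recs)
}

#' Global robustness rank table
#'
#' Ranks parameters within each response by increasing robustness index
#' (rank 1 = least robust, i.e. smallest index; NaN indices rank last; ties
#' take the average rank), sums ranks across responses, and orders the table
#' by the total, smallest first.
#'
#' @param records data frame with columns `parameter`, `response`, `RI`
#'   (long format; one row per parameter-response pair).
#' @return data frame, one row per parameter: per-response RI columns, a
#'   `total` rank column, ordered by increasing total.
#' @export
rank_table <- function(records) {
  stopifnot(nrow(records) >= 1L,
            all(c("parameter", "response", "RI") %in% names(records)))
  responses <- unique(records$response)
  params <- unique(records$parameter)
  ri <- matrix(NaN, length(params), length(responses),
               dimnames = list(params, responses))
  for (i in seq_len(nrow(records)))
    ri[records$parameter[i], records$response[i]] <- records$RI[i]
  rks <- apply(ri, 2, function(v) {
    v[is.nan(v)] <- Inf   # no deviation anywhere: maximally robust, ranks last
    rank(v, ties.method = "average")
  })
  rks <- matrix(rks, nrow = length(params))  # guard single-parameter drop
  total <- rowSums(rks)
  out <- data.frame(parameter = params, ri, total = total,
                    check.names = FALSE, row.names = NULL)
  out[order(out$total), , drop = FALSE]
}

#' One-at-a-time parameter sweep
#'
#' Runs `n_reps` seeded replicates at every swept value of one parameter,
#' all other parameters at their defaults, and collects per-run response
#' distributions. The sweep must contain the default value, which provides
#' the control distributions for boundary detection.
#'
#' @param param name of a numeric parameter in `base_config`.
#' @param values numeric vector of values to sweep (validated against the
#'   parameter's declared legal range).
#' @param n_reps replicates per value (500 for full experiments; reduced
#'   sweeps are legitimate but lower powered).
#' @param base_config an [eae_config()].
#' @param master_seed integer master seed; replicate seeds are derived per
#'   value and replicate index.
#' @param runner function `(config, n, master_seed) -> data.frame` of
#'   per-run responses; defaults to running the simulator via
#'   [run_group_responses()].
#' @return named list (names = values) of response data frames, with
#'   attributes `values`, `param`, and per-value config hashes.
#' @export
sweep_parameter <- function(param, values, n_reps, base_config,
                            master_seed = 1L, runner = run_group_responses) {
  if (!param %in% names(base_config))
    stop("unknown parameter: ", param)
  rng <- config_legal_range(param)
  if (any(values < rng[1] | values > rng[2]))
    stop("swept values outside the legal range [", rng[1], ", ", rng[2],
         "] of ", param)
  out <- vector("list", length(values))
  hashes <- character(length(values))
  for (i in seq_along(values)) {
    cfg <- base_config
    cfg[[param]] <- values[i]
    hashes[i] <- config_hash(cfg)
    out[[i]] <- runner(cfg, n_reps,
                       derive_seed(master_seed, paste0(param, "=", values[i])))
  }
  names(out) <- as.character(values)
  structure(out, values = values, param = param, config_hash = hashes)
}

#' Full robustness analysis over a set of parameters
#'
#' Convenience glue: sweeps each parameter one at a time, computes boundaries
#' and indices per response, and assembles the global rank table.
#'
#' @param params named list: parameter name -> numeric vector of swept values
#'   (each must include the parameter's default).
#' @param base_config an [eae_config()].
#' @param n_reps replicates per swept value.
#' @param master_seed integer master seed.
#' @param runner see [sweep_parameter()].
#' @return list with `records` (long data frame parameter/response/LB/UB/
#'   LI/UI/RI) and `table` (the global rank table).
#' @export
robustness_analysis <- function(params, base_config, n_reps = 100,
                                master_seed = 1L,
                                runner = run_group_responses) {
  recs <- lapply(names(params), function(p) {
    values <- params[[p]]
    sw <- sweep_parameter(p, values, n_reps, base_config, master_seed, runner)
    pr <- parameter_robustness(sw, values, default = base_config[[p]])
    pr$parameter <- p
    pr
  })
  records <- do.call(rbind, recs)
  list(records = records, table = rank_table(records))
}

#' Write a robustness record in the conventional column layout
#'
#' CSV with columns response, RI, LI, UI, LB, UB; NaN printed as ".".
#'
#' @param record data frame from [parameter_robustness()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_robustness_record <- function(record, path) {
  out <- record[, c("response", "RI", "LI", "UI", "LB", "UB")]
  for (cl in c("RI", "LI", "UI", "LB", "UB")) {
    v <- out[[cl]]
    out[[cl]] <- ifelse(is.nan(v), ".", format(v, trim = TRUE))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
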