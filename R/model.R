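#' Fit the depression-prevention decision model
#'
#' Evaluates the full decision-analytic model at the point estimates of a
#' parameter set: the screening decision tree, the quarterly three-state
#' Markov cohort for each of the three arms (risk algorithm plus prevention,
#' universal prevention, treatment as usual), the cost and QALY accounting,
#' and the incremental analysis with dominance flags at the chosen
#' willingness to pay.
#'
#' This is a deterministic (expected-value) run. For the probabilistic
#' sensitivity analysis, call [simulate()] on the returned object (or
#' [run_psa()] directly).
#'
#' @param params a `deprev_params` parameter set; defaults to
#'   [reference_parameters()].
#' @param wtp willingness to pay per QALY, GBP; defaults to the set's `wtp`.
#' @param or_scale how the odds ratio is translated into an absolute risk,
#'   `"risk"` (default) or `"odds"`; see [cycle_probability()].
#' @param half_cycle logical, half-cycle correction; defaults to the set's
#'   `half_cycle_correction` flag.
#' @return An object of class `deprev_model`: a list with `params`, `point`,
#'   `arms` (per-arm [evaluate_arm()] output), `economics` (per-arm
#'   [arm_economics()] output), `table` (the [incremental_analysis()]),
#'   `cases_prevented` (named, versus TAU) and the options used.
#' @examples
#' fit <- deprev_model()
#' fit
#' summary(fit)
#' coef(fit)["or_targeted"]
#' @seealso [simulate.deprev_model()], [ceac()], [run_scenario()]
#' @export
deprev_model <- function(params = reference_parameters(), wtp = NULL,
                         or_scale = c("risk", "odds"), half_cycle = NULL) {
  stopifnot(inherits(params, "deprev_params"))
  or_scale <- match.arg(or_scale)
  validate_parameters(params)
  point <- point_estimates(params)
  if (is.null(wtp)) wtp <- point$wtp
  if (is.null(half_cycle)) half_cycle <- isTRUE(point$half_cycle_correction)

  arms <- lapply(.deprev_arms, function(a)
    evaluate_arm(point, a, or_scale = or_scale, half_cycle = half_cycle))
  names(arms) <- .deprev_arms
  econ <- lapply(arms, arm_economics, point = point, wtp = wtp,
                 half_cycle = half_cycle)
  tab <- incremental_analysis(econ, wtp = wtp)
  cases <- vapply(arms, `[[`, numeric(1), "incident_cases")
  structure(list(
    params = params,
    point = point,
    arms = arms,
    economics = econ,
    table = tab,
    cases_prevented = cases[["tau"]] - cases[c("predictd_prevention",
                                               "universal_prevention")],
    wtp = wtp,
    or_scale = or_scale,
    half_cycle = half_cycle
  ), class = "deprev_model")
}

#' @export
print.deprev_model <- function(x, ...) {
  cat("Depression-prevention decision model (deterministic run)\n")
  cat(sprintf("  cohort %g per arm, %d quarterly cycles, annual incidence %.1f%%%s\n",
              x$point$cohort_size, x$point$horizon_cycles,
              100 * x$point$annual_incidence,
              if (x$half_cycle) ", half-cycle corrected" else ""))
  cat(sprintf("  screening Se %.3f / Sp %.3f at threshold %.3f; OR %.2f (targeted), %.2f (universal)\n",
              x$point$screening_sensitivity, x$point$screening_specificity,
              x$point$screening_threshold, x$point$or_targeted,
              x$point$or_universal))
  cat(sprintf("  cases prevented vs TAU: %.1f (risk algorithm + prevention), %.1f (universal)\n",
              x$cases_prevented[["predictd_prevention"]],
              x$cases_prevented[["universal_prevention"]]))
  best <- x$table$arm[x$table$optimal]
  cat(sprintf("  optimal arm at WTP GBP %s/QALY: %s\n",
              format(x$wtp, big.mark = ","), best))
  invisible(x)
}

#' Summary table of a fitted decision model
#'
#' @param object a `deprev_model`.
#' @param ... unused.
#' @return A `data.frame` with one row per arm: cost components, total cost,
#'   QALYs, incident cases, cases prevented vs TAU, NMB (cohort total and per
#'   patient) and flags, in the layout of a standard cost-effectiveness
#'   results table.
#' @export
summary.deprev_model <- function(object, ...) {
  econ <- object$economics
  df <- data.frame(
    arm = .deprev_arms,
    cost_screening = vapply(econ, `[[`, numeric(1), "cost_screening"),
    cost_programme = vapply(econ, `[[`, numeric(1), "cost_programme"),
    cost_treatment = vapply(econ, `[[`, numeric(1), "cost_treatment"),
    total_cost = vapply(econ, `[[`, numeric(1), "total_cost"),
    total_qalys = vapply(econ, `[[`, numeric(1), "total_qalys"),
    incident_cases = vapply(econ, `[[`, numeric(1), "incident_cases"),
    cases_prevented = c(0, object$cases_prevented[c("predictd_prevention",
                                                    "universal_prevention")])[
      match(.deprev_arms, c("tau", "predictd_prevention", "universal_prevention"))],
    nmb = vapply(econ, `[[`, numeric(1), "nmb"),
    per_patient_nmb = vapply(econ, `[[`, numeric(1), "per_patient_nmb"),
    strongly_dominated = object$table$strongly_dominated,
    optimal = object$table$optimal,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  class(df) <- c("summary.deprev_model", "data.frame")
  attr(df, "wtp") <- object$wtp
  df
}

#' @export
print.summary.deprev_model <- function(x, ...) {
  cat(sprintf("Costs, QALYs and NMB per cohort at WTP = GBP %s per QALY\n",
              format(attr(x, "wtp"), big.mark = ",")))
  df <- as.data.frame(x)
  num <- c("cost_screening", "cost_programme", "cost_treatment", "total_cost", "nmb")
  df[num] <- lapply(df[num], round)
  df$total_qalys <- round(df$total_qalys, 2)
  df$incident_cases <- round(df$incident_cases, 1)
  df$cases_prevented <- round(df$cases_prevented, 1)
  df$per_patient_nmb <- round(df$per_patient_nmb)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
coef.deprev_model <- function(object, ...) {
  p <- object$point
  vapply(p, function(v) if (is.logical(v)) as.numeric(v) else v, numeric(1))
}

#' Per-cycle state occupancies of a fitted model as a tidy data frame
#'
#' @param x a `deprev_model`.
#' @param ... unused.
#' @return A `data.frame` with columns `arm`, `group`, `cycle`, `state`,
#'   `expected_count`, suitable for CSV export or plotting.
#' @export
as.data.frame.deprev_model <- function(x, ...) {
  out <- do.call(rbind, lapply(names(x$arms), function(a) {
    ev <- x$arms[[a]]
    do.call(rbind, lapply(names(ev$groups), function(g) {
      df <- as.data.frame(ev$groups[[g]])
      cbind(arm = a, group = g, df, stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Simulate from the model: probabilistic sensitivity analysis
#'
#' `simulate()` on a fitted `deprev_model` reruns the whole pipeline `nsim`
#' times with parameters drawn from their uncertainty distributions — i.e. it
#' performs the probabilistic sensitivity analysis under the model's own
#' options. Equivalent to [run_psa()] on the model's parameter set.
#'
#' @param object a `deprev_model`.
#' @param nsim number of PSA draws.
#' @param seed integer RNG seed (required for reproducibility).
#' @param ... unused.
#' @return A `deprev_psa` object; see [run_psa()].
#' @export
simulate.deprev_model <- function(object, nsim = 10000, seed = 1, ...) {
  run_psa(object$params, n_sims = nsim, seed = seed, wtp = object$wtp,
          or_scale = object$or_scale, half_cycle = object$half_cycle)
}
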