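# Decision tree and quarterly three-state Markov cohort engine. The cohort is
# tracked in expected (fractional) patients; counts are rounded only when
# reported. States: no major depression -> depressed -> recovered, with the
# recovered state absorbing over the 12-month horizon (no relapse arrow).

.deprev_arms <- c("tau", "predictd_prevention", "universal_prevention")
.deprev_states <- c("no_major_depression", "depressed", "recovered")

#' Stratify a cohort by screening result
#'
#' Expected-value split of a cohort into true/false positives/negatives given
#' the 12-month incidence and the screening instrument's sensitivity and
#' specificity, with the implied baseline 12-month risks of each group: the
#' positive predictive value for screen-positives and `fn / (tn + fn)` for
#' screen-negatives.
#'
#' @param n cohort size.
#' @param incidence_12m 12-month probability of developing depression.
#' @param sensitivity,specificity screening performance at the chosen
#'   risk-score threshold.
#' @return A list of class `deprev_strata` with expected counts `tp`, `fp`,
#'   `tn`, `fn` and risks `high_risk_baseline_12m`, `low_risk_baseline_12m`.
#' @examples
#' stratify_cohort(1000, 0.088, 0.506, 0.8)
#' @export
stratify_cohort <- function(n, incidence_12m, sensitivity, specificity) {
  stopifnot(n > 0, incidence_12m >= 0, incidence_12m < 1,
            sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  tp <- n * incidence_12m * sensitivity
  fn <- n * incidence_12m * (1 - sensitivity)
  fp <- n * (1 - incidence_12m) * (1 - specificity)
  tn <- n * (1 - incidence_12m) * specificity
  pos <- tp + fp
  neg <- tn + fn
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    high_risk_baseline_12m = if (pos > 0) tp / pos else 0,
    low_risk_baseline_12m = if (neg > 0) fn / neg else 0
  ), class = "deprev_strata")
}

#' Per-cycle incidence probability under a prevention effect
#'
#' Applies an odds ratio to a group's baseline 12-month risk, mixes treated
#' and untreated risk by programme uptake, and decomposes the effective
#' 12-month risk into a constant quarterly transition probability via the
#' rate conversion of [prob_to_rate()]/[rate_to_prob()].
#'
#' Two conventions for translating the OR into an absolute risk are provided.
#' `"risk"` (the default) applies the OR multiplicatively to the baseline
#' risk, treating it as a risk ratio — the convention under which the model
#' reproduces the published case counts for this decision problem.
#' `"odds"` is the odds-scale conversion of [apply_odds_ratio()]. The two
#' agree closely for rare outcomes and diverge as the baseline risk grows;
#' see the methods vignette.
#'
#' @param baseline_12m baseline 12-month risk of the group.
#' @param or treatment-effect odds ratio (1 = no effect).
#' @param uptake proportion of the group that accesses the programme.
#' @param or_scale `"risk"` or `"odds"` (see Details).
#' @param cycle_months cycle length in months.
#' @param horizon_months horizon over which `baseline_12m` is defined.
#' @return Quarterly (per-cycle) incidence probability.
#' @examples
#' cycle_probability(0.088, or = 1)            # untreated quarterly risk
#' cycle_probability(0.196, or = 0.66, or_scale = "odds")
#' @export
cycle_probability <- function(baseline_12m, or = 1, uptake = 1,
                              or_scale = c("risk", "odds"),
                              cycle_months = 3, horizon_months = 12) {
  or_scale <- match.arg(or_scale)
  stopifnot(baseline_12m >= 0, baseline_12m <= 1, or >= 0,
            uptake >= 0, uptake <= 1)
  treated <- switch(or_scale,
    # odds scale: a baseline of 1 has infinite odds and stays at 1 (the
    # degenerate perfect-screen group)
    odds = if (baseline_12m == 1) 1 else apply_odds_ratio(baseline_12m, or),
    risk = {
      r <- baseline_12m * or
      if (r > 1) stop("risk-scale effect pushes the treated risk above 1; ",
                      "use or_scale = \"odds\" for odds ratios above 1 at high baseline risk")
      r
    }
  )
  effective <- uptake * treated + (1 - uptake) * baseline_12m
  if (effective >= 1) return(1)  # certain onset: every cycle's survivors convert
  rescale_probability(effective, from = horizon_months, to = cycle_months)
}

#' Run the three-state Markov cohort recursion
#'
#' Rolls a homogeneous group forward through the states no major depression,
#' depressed and recovered. Per cycle, a fraction `q_incidence` of the
#' well group develops depression and a fraction `q_recovery` of those
#' depressed at the start of the cycle recovers; the recovered state is
#' absorbing. A patient therefore spends at least one full cycle depressed.
#' Incident cases accumulate as the new entrants to the depressed state.
#'
#' State-during-cycle accounting attributes the whole transition cycle to the
#' destination state (onset at cycle start). With `half_cycle = TRUE`, new
#' entrants instead contribute half of their entry cycle to the depressed
#' state and half to the well state, which lowers depressed person-time and
#' raises QALYs downstream.
#'
#' @param group_size number of patients starting in the well state.
#' @param q_incidence per-cycle probability of developing depression.
#' @param q_recovery per-cycle probability of recovering once depressed.
#' @param cycles number of cycles to run.
#' @param half_cycle apply the half-cycle correction to entry cycles.
#' @return An object of class `deprev_trajectory`: `occupancy` (matrix,
#'   cycles 0..n by state), `new_cases` (per-cycle incident entrants),
#'   `cumulative_incident_cases` (vector over cycles),
#'   `person_cycles_depressed` (half-cycle-adjusted when enabled), and the
#'   inputs.
#' @examples
#' run_markov(1000, 0.02276, 0.293, cycles = 4)
#' @export
run_markov <- function(group_size, q_incidence, q_recovery, cycles = 4,
                       half_cycle = FALSE) {
  stopifnot(group_size >= 0, cycles >= 1,
            q_incidence >= 0, q_incidence <= 1,
            q_recovery >= 0, q_recovery <= 1)
  occ <- matrix(0, nrow = cycles + 1, ncol = 3,
                dimnames = list(cycle = 0:cycles, state = .deprev_states))
  occ[1, 1] <- group_size
  new_cases <- numeric(cycles)
  well <- group_size; dep <- 0; rec <- 0
  for (t in seq_len(cycles)) {
    onset <- well * q_incidence
    recov <- dep * q_recovery
    well <- well - onset
    dep <- dep - recov + onset
    rec <- rec + recov
    occ[t + 1, ] <- c(well, dep, rec)
    new_cases[t] <- onset
  }
  person_cycles <- sum(occ[-1, "depressed"])
  if (half_cycle) person_cycles <- person_cycles - 0.5 * sum(new_cases)
  structure(list(
    occupancy = occ,
    new_cases = new_cases,
    cumulative_incident_cases = cumsum(new_cases),
    person_cycles_depressed = person_cycles,
    group_size = group_size,
    cycles = cycles,
    half_cycle = half_cycle
  ), class = "deprev_trajectory")
}

#' @export
print.deprev_trajectory <- function(x, ...) {
  cat(sprintf("Markov cohort trajectory: %.4g patients, %d quarterly cycles%s\n",
              x$group_size, x$cycles,
              if (x$half_cycle) " (half-cycle corrected)" else ""))
  print(round(x$occupancy, 2))
  cat(sprintf("Cumulative incident cases: %.2f; depressed person-cycles: %.2f\n",
              x$cumulative_incident_cases[x$cycles], x$person_cycles_depressed))
  invisible(x)
}

#' @export
as.data.frame.deprev_trajectory <- function(x, row.names = NULL, optional = FALSE, ...) {
  occ <- x$occupancy
  data.frame(
    cycle = rep(as.integer(rownames(occ)), times = ncol(occ)),
    state = rep(colnames(occ), each = nrow(occ)),
    expected_count = as.vector(occ),
    stringsAsFactors = FALSE
  )
}

#' Evaluate one treatment arm of the decision tree
#'
#' Runs the decision tree and Markov engine for one arm under a set of point
#' parameter values:
#' \describe{
#'   \item{`tau`}{no screening, no prevention: one untreated cohort run at the
#'     population incidence.}
#'   \item{`predictd_prevention`}{the cohort is stratified by the risk
#'     algorithm; screen-positives receive the prevention programme (targeted
#'     OR applied to their PPV-implied baseline risk), screen-negatives run
#'     untreated at their residual risk.}
#'   \item{`universal_prevention`}{one run over the whole cohort with the
#'     universal OR, attenuated by the universal uptake proportion.}
#' }
#'
#' @param point named list of parameter values (see [point_estimates()]).
#' @param arm one of `"tau"`, `"predictd_prevention"`,
#'   `"universal_prevention"`.
#' @param or_scale effect-translation convention, see [cycle_probability()].
#' @param half_cycle apply the half-cycle correction.
#' @return A list of class `deprev_arm_eval`: `arm`, `groups` (named list of
#'   `deprev_trajectory`), `incident_cases` (total expected cases),
#'   `programme_recipients` (patients incurring programme cost), `screened`
#'   (whether the arm pays the screening cost), and `strata` for the
#'   stratified arm.
#' @examples
#' p <- point_estimates(reference_parameters())
#' evaluate_arm(p, "predictd_prevention")$incident_cases
#' @export
evaluate_arm <- function(point, arm = .deprev_arms,
                         or_scale = c("risk", "odds"), half_cycle = NULL) {
  arm <- match.arg(arm)
  or_scale <- match.arg(or_scale)
  p <- point
  if (is.null(half_cycle)) half_cycle <- isTRUE(p$half_cycle_correction)
  q_rec <- rescale_probability(p$recovery_prob_6m, from = 6, to = 3)
  strata <- NULL
  if (arm == "tau") {
    q <- cycle_probability(p$annual_incidence, or = 1, uptake = 1, or_scale = or_scale)
    groups <- list(all = run_markov(p$cohort_size, q, q_rec,
                                    p$horizon_cycles, half_cycle))
    recipients <- 0
    screened <- FALSE
  } else if (arm == "predictd_prevention") {
    strata <- stratify_cohort(p$cohort_size, p$annual_incidence,
                              p$screening_sensitivity, p$screening_specificity)
    q_pos <- cycle_probability(strata$high_risk_baseline_12m, or = p$or_targeted,
                               uptake = 1, or_scale = or_scale)
    q_neg <- cycle_probability(strata$low_risk_baseline_12m, or = 1,
                               uptake = 1, or_scale = or_scale)
    groups <- list(
      screen_positive = run_markov(strata$tp + strata$fp, q_pos, q_rec,
                                   p$horizon_cycles, half_cycle),
      screen_negative = run_markov(strata$tn + strata$fn, q_neg, q_rec,
                                   p$horizon_cycles, half_cycle)
    )
    recipients <- strata$tp + strata$fp
    screened <- TRUE
  } else {
    q <- cycle_probability(p$annual_incidence, or = p$or_universal,
                           uptake = p$universal_uptake, or_scale = or_scale)
    groups <- list(all = run_markov(p$cohort_size, q, q_rec,
                                    p$horizon_cycles, half_cycle))
    recipients <- p$universal_uptake * p$cohort_size
    screened <- FALSE
  }
  cases <- sum(vapply(groups, function(g)
    g$cumulative_incident_cases[g$cycles], numeric(1)))
  structure(list(
    arm = arm, groups = groups, incident_cases = cases,
    programme_recipients = recipients, screened = screened,
    strata = strata, half_cycle = half_cycle
  ), class = "deprev_arm_eval")
}
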