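# Cost and QALY accounting from the NHS perspective over a 12-month horizon:
# no discounting; annual costs and utilities are divided by four so each
# quarterly cycle carries three months' worth.

#' Cost of administering the risk algorithm to a cohort
#'
#' Nurse time per patient at an hourly unit cost, plus a one-off training
#' cost: `n * (minutes/60) * hourly + training`.
#'
#' @param n number of patients screened.
#' @param minutes_per_patient nurse minutes to administer the instrument once.
#' @param nurse_cost_per_hour nurse unit cost, GBP/hour.
#' @param training_cost one-off training cost, GBP.
#' @return Total screening-programme cost in GBP.
#' @examples
#' screening_cost(1000, 15, 42, 2000)  # 12500
#' @export
screening_cost <- function(n, minutes_per_patient, nurse_cost_per_hour,
                           training_cost = 0) {
  stopifnot(n >= 0, minutes_per_patient >= 0, nurse_cost_per_hour >= 0,
            training_cost >= 0)
  n * (minutes_per_patient / 60) * nurse_cost_per_hour + training_cost
}

#' Weighted average annual treatment cost
#'
#' Combines a treatment mix into a single annual cost per depressed patient:
#' the sum of each treatment's proportion times its average annual cost.
#' Proportions may sum to less than 1; the remainder receives no treatment at
#' zero cost.
#'
#' @param proportions proportion of depressed patients accessing each
#'   treatment type.
#' @param annual_costs average annual cost of each treatment type, GBP.
#' @return Weighted annual cost, GBP/year.
#' @examples
#' weighted_treatment_cost(c(0.5, 0.25), c(100, 400))  # 150
#' @export
weighted_treatment_cost <- function(proportions, annual_costs) {
  if (length(proportions) != length(annual_costs))
    stop("'proportions' and 'annual_costs' must have the same length")
  if (!length(proportions)) return(0)
  stopifnot(all(proportions >= 0), all(annual_costs >= 0))
  if (sum(proportions) > 1 + 1e-12)
    stop("treatment-mix proportions sum above 1 (", format(sum(proportions)), ")")
  sum(proportions * annual_costs)
}

# Depressed person-cycles of a trajectory under a given half-cycle setting,
# recomputed from the raw occupancies so one Markov run can serve both
# accounting variants.
person_cycles_depressed <- function(traj, half_cycle) {
  pc <- sum(traj$occupancy[-1, "depressed"])
  if (half_cycle) pc <- pc - 0.5 * sum(traj$new_cases)
  pc
}

#' Costs, QALYs and net monetary benefit of one arm
#'
#' Accumulates, over all risk groups of an evaluated arm:
#' \itemize{
#'   \item treatment cost: depressed person-cycles times a quarter of the
#'     annual treatment cost (patients are costed for each full quarter spent
#'     depressed; the recovered state carries no treatment cost);
#'   \item programme cost: programme recipients times the per-patient
#'     programme cost (screen-positives in the targeted arm, the uptake
#'     fraction of the cohort in the universal arm, nobody under TAU);
#'   \item screening cost, in the targeted arm only;
#'   \item QALYs: per cycle, state occupancy times the state utility divided
#'     by four, with the half-cycle correction crediting new depression
#'     entrants half a cycle of well-state utility.
#' }
#' NMB is `wtp * QALYs - total cost`. No discounting is applied over the
#' 12-month horizon.
#'
#' @param arm_eval a `deprev_arm_eval` from [evaluate_arm()].
#' @param point named list of parameter values.
#' @param wtp willingness to pay per QALY, GBP; defaults to `point$wtp`.
#' @param half_cycle half-cycle accounting; defaults to the setting the arm
#'   was evaluated with.
#' @return A list of class `deprev_arm_result`: `arm`, cost components,
#'   `total_cost`, `total_qalys`, `incident_cases`, `nmb`, `per_patient_nmb`.
#' @export
arm_economics <- function(arm_eval, point, wtp = NULL, half_cycle = NULL) {
  stopifnot(inherits(arm_eval, "deprev_arm_eval"))
  p <- point
  if (is.null(wtp)) wtp <- p$wtp
  if (is.null(half_cycle)) half_cycle <- arm_eval$half_cycle

  u <- c(no_major_depression = p$utility_well,
         depressed = p$utility_depressed,
         recovered = p$utility_recovered)
  qalys <- 0
  pc_dep <- 0
  for (g in arm_eval$groups) {
    occ <- g$occupancy[-1, , drop = FALSE]
    qalys <- qalys + sum(occ %*% u) / 4
    if (half_cycle)
      qalys <- qalys + 0.5 * sum(g$new_cases) *
        (p$utility_well - p$utility_depressed) / 4
    pc_dep <- pc_dep + person_cycles_depressed(g, half_cycle)
  }
  cost_treatment <- pc_dep * p$annual_treatment_cost / 4
  cost_programme <- arm_eval$programme_recipients * p$programme_cost_per_patient
  cost_screening <- if (arm_eval$screened) {
    screening_cost(p$cohort_size, p$nurse_minutes_per_patient,
                   p$nurse_cost_per_hour, p$training_cost)
  } else 0
  total_cost <- cost_treatment + cost_programme + cost_screening
  nmb <- wtp * qalys - total_cost
  structure(list(
    arm = arm_eval$arm,
    cost_screening = cost_screening,
    cost_programme = cost_programme,
    cost_treatment = cost_treatment,
    total_cost = total_cost,
    total_qalys = qalys,
    incident_cases = arm_eval$incident_cases,
    wtp = wtp,
    nmb = nmb,
    per_patient_nmb = nmb / p$cohort_size
  ), class = "deprev_arm_result")
}

#' Incremental analysis across the three arms
#'
#' Tabulates costs, QALYs and cases per arm, increments versus TAU, strong
#' dominance (an arm is strongly dominated if some other arm has strictly
#' lower cost and strictly higher QALYs) and the NMB-optimal arm at the
#' stated willingness to pay.
#'
#' @param results list of `deprev_arm_result`, one per arm.
#' @param wtp willingness to pay per QALY; defaults to the one the results
#'   were computed at.
#' @return A `data.frame` of class `deprev_incremental` with one row per arm:
#'   `total_cost`, `total_qalys`, `incident_cases`, `inc_cost`, `inc_qalys`
#'   (vs TAU), `nmb`, `strongly_dominated`, `optimal`.
#' @export
incremental_analysis <- function(results, wtp = NULL) {
  stopifnot(all(vapply(results, inherits, logical(1), "deprev_arm_result")))
  arms <- vapply(results, `[[`, character(1), "arm")
  names(results) <- arms
  if (!all(.deprev_arms %in% arms))
    stop("incremental analysis needs all three arms; missing: ",
         paste(setdiff(.deprev_arms, arms), collapse = ", "))
  results <- results[.deprev_arms]
  cost <- vapply(results, `[[`, numeric(1), "total_cost")
  qalys <- vapply(results, `[[`, numeric(1), "total_qalys")
  cases <- vapply(results, `[[`, numeric(1), "incident_cases")
  if (is.null(wtp)) wtp <- results[[1]]$wtp
  nmb <- wtp * qalys - cost
  dominated <- vapply(seq_along(cost), function(i)
    any(cost < cost[i] & qalys > qalys[i]), logical(1))
  tab <- data.frame(
    arm = .deprev_arms,
    total_cost = cost,
    total_qalys = qalys,
    incident_cases = cases,
    inc_cost = cost - cost[["tau"]],
    inc_qalys = qalys - qalys[["tau"]],
    nmb = nmb,
    strongly_dominated = dominated,
    optimal = seq_along(nmb) == which.max(nmb),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  attr(tab, "wtp") <- wtp
  class(tab) <- c("deprev_incremental", "data.frame")
  tab
}

#' @export
print.deprev_incremental <- function(x, ...) {
  cat(sprintf("Incremental analysis at WTP = GBP %s per QALY\n",
              format(attr(x, "wtp"), big.mark = ",")))
  df <- as.data.frame(x)
  df$total_cost <- round(df$total_cost)
  df$inc_cost <- round(df$inc_cost)
  df$total_qalys <- round(df$total_qalys, 2)
  df$inc_qalys <- round(df$inc_qalys, 2)
  df$incident_cases <- round(df$incident_cases, 1)
  df$nmb <- round(df$nmb)
  print(df, row.names = FALSE)
  invisible(x)
}
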