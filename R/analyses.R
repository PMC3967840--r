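# Scenario and threshold analyses around the base case: alternative
# treatment-effect odds ratios, risk-score threshold variants, the maximum
# affordable programme cost as a function of effectiveness, the
# universal-uptake sweep, and the half-cycle-correction comparison. Paired
# comparisons share random draws (common random numbers) to cut Monte Carlo
# variance.

#' Define a scenario as overrides on a parameter set
#'
#' @param label scenario name.
#' @param ... named overrides in the form accepted by [set_parameters()].
#' @return An object of class `deprev_scenario`.
#' @examples
#' s <- scenario("gp_only", or_targeted = list(value = 0.6, ci_low = 0.3, ci_high = 1.2))
#' @export
scenario <- function(label, ...) {
  overrides <- list(...)
  if (length(overrides) && (is.null(names(overrides)) || any(!nzchar(names(overrides)))))
    stop("scenario overrides must be named")
  structure(list(label = label, overrides = overrides), class = "deprev_scenario")
}

#' @export
print.deprev_scenario <- function(x, ...) {
  cat("Scenario:", x$label, "\n")
  if (!length(x$overrides)) {
    cat("  (no overrides: base case)\n")
  } else {
    for (nm in names(x$overrides)) {
      ov <- x$overrides[[nm]]
      cat(sprintf("  %s = %s\n", nm,
                  if (is.list(ov)) paste(names(ov), unlist(ov), sep = "=", collapse = ", ")
                  else format(ov)))
    }
  }
  invisible(x)
}

#' Named scenario presets
#'
#' The standard sensitivity analyses of the decision problem:
#' \describe{
#'   \item{`gp_only`}{pooled OR restricted to studies recruiting from GP
#'     lists: 0.6 (95% CI 0.3–1.2).}
#'   \item{`ip`}{interpersonal-therapy programmes: OR 0.13 (95% CI
#'     0.04–0.42).}
#'   \item{`non_ip`}{all programmes excluding interpersonal therapy: OR 0.75
#'     (95% CI 0.58–0.98).}
#'   \item{`threshold_0.154`}{risk-score threshold 0.154: sensitivity 0.458,
#'     specificity 0.85.}
#'   \item{`threshold_0.183`}{risk-score threshold 0.183: sensitivity 0.373,
#'     specificity 0.9.}
#' }
#'
#' @return Named list of `deprev_scenario` objects.
#' @export
scenario_presets <- function() {
  list(
    gp_only = scenario("gp_only",
      or_targeted = list(value = 0.6, ci_low = 0.3, ci_high = 1.2)),
    ip = scenario("ip",
      or_targeted = list(value = 0.13, ci_low = 0.04, ci_high = 0.42)),
    non_ip = scenario("non_ip",
      or_targeted = list(value = 0.75, ci_low = 0.58, ci_high = 0.98)),
    `threshold_0.154` = scenario("threshold_0.154",
      screening_threshold = 0.154,
      screening_sensitivity = 0.458,
      screening_specificity = 0.85),
    `threshold_0.183` = scenario("threshold_0.183",
      screening_threshold = 0.183,
      screening_sensitivity = 0.373,
      screening_specificity = 0.9)
  )
}

#' Apply a scenario to a parameter set
#'
#' @param params a `deprev_params` object.
#' @param s a `deprev_scenario`.
#' @return The overridden, validated `deprev_params`.
#' @export
apply_scenario <- function(params, s) {
  stopifnot(inherits(s, "deprev_scenario"))
  if (!length(s$overrides)) return(params)
  do.call(set_parameters, c(list(params), s$overrides))
}

#' Run the full pipeline under a scenario
#'
#' Applies the scenario's overrides to the base parameter set, then runs the
#' deterministic model, the PSA and the CEAC.
#'
#' @param s a `deprev_scenario` (or a preset name, see [scenario_presets()]).
#' @param params base parameter set.
#' @param n_sims number of PSA draws.
#' @param seed RNG seed.
#' @param wtp_grid CEAC willingness-to-pay grid.
#' @param ... further options passed to [deprev_model()] and [run_psa()]
#'   (`wtp`, `or_scale`, `half_cycle`).
#' @return A list of class `deprev_scenario_result`: `scenario`, `model`
#'   (deterministic run), `psa`, `ceac`, `table` (incremental analysis) and
#'   `mean_cases_prevented`.
#' @export
run_scenario <- function(s, params = reference_parameters(), n_sims = 1000,
                         seed = 1, wtp_grid = seq(0, 50000, by = 1000), ...) {
  if (is.character(s)) {
    presets <- scenario_presets()
    if (!s %in% names(presets)) stop("unknown scenario preset: ", s)
    s <- presets[[s]]
  }
  sp <- apply_scenario(params, s)
  model <- deprev_model(sp, ...)
  psa <- run_psa(sp, n_sims = n_sims, seed = seed, ...)
  structure(list(
    scenario = s,
    model = model,
    psa = psa,
    ceac = ceac(psa, wtp_grid),
    table = model$table,
    mean_cases_prevented = colMeans(psa$cases_prevented)
  ), class = "deprev_scenario_result")
}

#' @export
print.deprev_scenario_result <- function(x, ...) {
  print(x$scenario)
  cat(sprintf("  PSA (%d draws): mean cases prevented %.1f (targeted), %.1f (universal)\n",
              x$psa$n_sims,
              x$mean_cases_prevented[["predictd_prevention"]],
              x$mean_cases_prevented[["universal_prevention"]]))
  print(x$table)
  invisible(x)
}

#' Maximum affordable programme cost for a given effectiveness
#'
#' Finds, by bisection, the per-patient programme cost at which the targeted
#' prevention arm's mean net monetary benefit equals the better of the other
#' two arms, i.e. the root of
#' `f(c) = mean NMB_targeted(c) - mean max(NMB_tau, NMB_universal)`,
#' averaged over `reps` PSA draws with the targeted OR held fixed at `or`.
#' All other parameters are drawn from their distributions; the same draws
#' are reused for every candidate cost, so `f` is exactly linear and
#' decreasing in `c`. A negative root means the programme cannot be
#' cost-effective at any positive price for that effectiveness.
#'
#' @param or targeted-programme odds ratio, in `(0, 1]`.
#' @param wtp willingness to pay per QALY.
#' @param reps PSA draws per evaluation.
#' @param seed RNG seed.
#' @param params base parameter set.
#' @param bracket search interval for the cost, GBP.
#' @param tol absolute tolerance on the root, GBP.
#' @param ... options passed to [evaluate_arm()] (`or_scale`, `half_cycle`).
#' @return A list: `max_cost` (GBP; `Inf`/`-Inf` when no root lies in the
#'   bracket), `f_at_root`, `feasible` (root found within the bracket),
#'   `or`, `reps`.
#' @examples
#' max_affordable_cost(0.66, reps = 20, seed = 1)$max_cost
#' @export
max_affordable_cost <- function(or, wtp = 20000, reps = 100, seed = 1,
                                params = reference_parameters(),
                                bracket = c(-500, 1000), tol = 0.01, ...) {
  stopifnot(or > 0, or <= 1, wtp > 0, reps >= 1, bracket[1] < bracket[2])
  params <- set_parameters(params, or_targeted = list(value = or, family = "fixed",
                                                      ci_low = NA_real_,
                                                      ci_high = NA_real_))
  set.seed(seed)
  nmb_pred0 <- recipients <- nmb_other <- numeric(reps)
  for (i in seq_len(reps)) {
    draw <- sample_parameters(params)
    evs <- lapply(.deprev_arms, function(a) evaluate_arm(draw, a, ...))
    names(evs) <- .deprev_arms
    ecs <- lapply(evs, arm_economics, point = draw, wtp = wtp)
    # NMB of the targeted arm is linear in the programme cost c:
    #   nmb(c) = nmb(at drawn cost) + recipients * (drawn cost - c)
    nmb_pred0[i] <- ecs$predictd_prevention$nmb +
      evs$predictd_prevention$programme_recipients * draw$programme_cost_per_patient
    recipients[i] <- evs$predictd_prevention$programme_recipients
    nmb_other[i] <- max(ecs$tau$nmb, ecs$universal_prevention$nmb)
  }
  f <- function(c) mean(nmb_pred0 - recipients * c - nmb_other)
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- f(lo); f_hi <- f(hi)
  if (f_lo < 0)  # even a subsidy cannot rescue the programme
    return(list(max_cost = -Inf, f_at_root = NA_real_, feasible = FALSE,
                or = or, reps = reps))
  if (f_hi > 0)  # affordable beyond the bracket
    return(list(max_cost = Inf, f_at_root = NA_real_, feasible = FALSE,
                or = or, reps = reps))
  while (hi - lo > tol / 2) {
    mid <- (lo + hi) / 2
    if (f(mid) >= 0) lo <- mid else hi <- mid
  }
  # f is exactly linear in c for the cached draws; one secant step on the
  # final bracket sharpens the root to machine precision.
  f_lo <- f(lo); f_hi <- f(hi)
  root <- if (f_lo == f_hi) (lo + hi) / 2 else lo + (hi - lo) * f_lo / (f_lo - f_hi)
  list(max_cost = root, f_at_root = f(root), feasible = TRUE, or = or,
       reps = reps)
}

#' Maximum affordable programme cost across an effectiveness grid
#'
#' @param or_grid odds-ratio grid (default 0.01 to 1 in steps of 0.01).
#' @param wtp,reps,seed,params,... as in [max_affordable_cost()]; draws are
#'   redrawn per grid point from seeds derived from `seed`.
#' @return A `data.frame` with columns `or`, `max_cost`, `feasible`.
#' @export
max_cost_curve <- function(or_grid = seq(0.01, 1, by = 0.01), wtp = 20000,
                           reps = 100, seed = 1,
                           params = reference_parameters(), ...) {
  res <- lapply(seq_along(or_grid), function(k)
    max_affordable_cost(or_grid[k], wtp = wtp, reps = reps,
                        seed = seed + k - 1L, params = params, ...))
  data.frame(
    or = or_grid,
    max_cost = vapply(res, `[[`, numeric(1), "max_cost"),
    feasible = vapply(res, `[[`, logical(1), "feasible")
  )
}

#' Probability each arm is optimal across universal-uptake values
#'
#' Sweeps the proportion of patients accessing the universal programme over a
#' grid, holding everything else at the base case, and reports the
#' probability each arm attains the highest NMB at the given willingness to
#' pay. The same `reps` PSA draws are shared across all uptake values
#' (common random numbers), and the TAU and targeted arms — which do not
#' depend on uptake — are evaluated once per draw.
#'
#' @param uptake_grid uptake proportions in `[0, 1]`.
#' @param reps PSA draws per uptake value.
#' @param seed RNG seed.
#' @param wtp willingness to pay per QALY; defaults to the parameter set's.
#' @param params base parameter set.
#' @param ... options passed to [evaluate_arm()].
#' @return A list of class `deprev_uptake_sweep`: `grid` (data frame with
#'   `uptake` and per-arm probabilities) and `crossover_uptake`, the largest
#'   uptake at which the universal arm's probability of being optimal
#'   exceeds the targeted arm's (`NA` if it never does).
#' @export
uptake_sweep <- function(uptake_grid = seq(0, 1, by = 0.01), reps = 100,
                         seed = 1, wtp = NULL,
                         params = reference_parameters(), ...) {
  stopifnot(all(uptake_grid >= 0), all(uptake_grid <= 1), reps >= 1)
  validate_parameters(params)
  if (is.null(wtp)) wtp <- point_estimates(params)$wtp
  set.seed(seed)
  draws <- replicate(reps, sample_parameters(params), simplify = FALSE)
  fixed_nmb <- vapply(draws, function(draw) {
    vapply(c("tau", "predictd_prevention"), function(a) {
      arm_economics(evaluate_arm(draw, a, ...), draw, wtp = wtp)$nmb
    }, numeric(1))
  }, numeric(2))  # 2 x reps
  probs <- t(vapply(uptake_grid, function(u) {
    win <- matrix(0, reps, 3, dimnames = list(NULL, .deprev_arms))
    for (i in seq_len(reps)) {
      draw <- draws[[i]]
      draw$universal_uptake <- u
      nmb_u <- arm_economics(evaluate_arm(draw, "universal_prevention", ...),
                             draw, wtp = wtp)$nmb
      nmb <- c(fixed_nmb["tau", i], fixed_nmb["predictd_prevention", i], nmb_u)
      best <- nmb == max(nmb)
      win[i, ] <- best / sum(best)
    }
    colMeans(win)
  }, numeric(3)))
  grid <- data.frame(uptake = uptake_grid, probs)
  over <- grid$universal_prevention > grid$predictd_prevention
  crossover <- if (any(over)) max(grid$uptake[over]) else NA_real_
  structure(list(grid = grid, crossover_uptake = crossover, wtp = wtp,
                 reps = reps, seed = seed),
            class = "deprev_uptake_sweep")
}

#' @export
print.deprev_uptake_sweep <- function(x, ...) {
  cat(sprintf("Universal-uptake sweep: %d uptake values, %d draws each, WTP GBP %s\n",
              nrow(x$grid), x$reps, format(x$wtp, big.mark = ",")))
  if (is.na(x$crossover_uptake)) {
    cat("  universal prevention never overtakes the targeted arm on this grid\n")
  } else {
    cat(sprintf("  universal prevention is the likelier optimum at uptake <= %.0f%%\n",
                100 * x$crossover_uptake))
  }
  invisible(x)
}

#' Paired comparison of base-case and half-cycle-corrected accounting
#'
#' Evaluates every PSA draw under both accounting variants (identical
#' transition dynamics, common random numbers): the base case attributes the
#' full entry cycle to the depressed state, the corrected variant half of it.
#' The correction strictly lowers depressed person-time — hence treatment
#' cost — and raises QALYs, in every draw.
#'
#' @param params base parameter set.
#' @param n_sims number of draws.
#' @param seed RNG seed.
#' @param wtp willingness to pay per QALY; defaults to the parameter set's.
#' @param or_scale effect-translation convention.
#' @return A list of class `deprev_half_cycle`: per-draw NMB matrices `base`
#'   and `corrected` (one column per arm), `delta_nmb`, per-draw cost and
#'   QALY matrices for both variants, and mean summaries.
#' @export
half_cycle_comparison <- function(params = reference_parameters(),
                                  n_sims = 1000, seed = 1, wtp = NULL,
                                  or_scale = c("risk", "odds")) {
  or_scale <- match.arg(or_scale)
  validate_parameters(params)
  if (is.null(wtp)) wtp <- point_estimates(params)$wtp
  arms <- .deprev_arms
  mk <- function() matrix(NA_real_, n_sims, length(arms),
                          dimnames = list(NULL, arms))
  nmb_b <- nmb_c <- cost_b <- cost_c <- q_b <- q_c <- mk()
  set.seed(seed)
  for (i in seq_len(n_sims)) {
    draw <- sample_parameters(params)
    for (a in arms) {
      ev <- evaluate_arm(draw, a, or_scale = or_scale, half_cycle = FALSE)
      eb <- arm_economics(ev, draw, wtp = wtp, half_cycle = FALSE)
      ec <- arm_economics(ev, draw, wtp = wtp, half_cycle = TRUE)
      cost_b[i, a] <- eb$total_cost; cost_c[i, a] <- ec$total_cost
      q_b[i, a] <- eb$total_qalys;   q_c[i, a] <- ec$total_qalys
      nmb_b[i, a] <- eb$nmb;         nmb_c[i, a] <- ec$nmb
    }
  }
  structure(list(
    base = nmb_b, corrected = nmb_c, delta_nmb = nmb_c - nmb_b,
    cost_base = cost_b, cost_corrected = cost_c,
    qalys_base = q_b, qalys_corrected = q_c,
    mean_nmb = rbind(base = colMeans(nmb_b), corrected = colMeans(nmb_c)),
    wtp = wtp, n_sims = n_sims, seed = seed
  ), class = "deprev_half_cycle")
}

#' @export
print.deprev_half_cycle <- function(x, ...) {
  cat(sprintf("Half-cycle correction, %d paired draws at WTP GBP %s/QALY\n",
              x$n_sims, format(x$wtp, big.mark = ",")))
  cat("Mean cohort NMB (GBP):\n")
  print(round(x$mean_nmb))
  cat("Mean NMB change from correction:\n")
  print(round(colMeans(x$delta_nmb), 1))
  invisible(x)
}
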