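# Probabilistic sensitivity analysis: one shared RNG stream, parameters drawn
# in alphabetical order of their names so results are seed-stable across
# refactors that reorder the parameter list.

#' Draw one parameter set from its uncertainty distributions
#'
#' Samples every non-fixed parameter from its fitted family — beta
#' (method-of-moments from mean and SE) for probabilities and utilities,
#' gamma for costs, log-normal for odds ratios (log-SD from the 95% CI when
#' given, else the delta-method `se/mean`) — and passes fixed parameters
#' through. Parameters without a reported SE use the SE-equals-mean
#' convention (see [reference_parameters()]). Draws violating the joint
#' invariants (for example a sampled recovered utility above the sampled well
#' utility) are rejected and redrawn, so every returned draw is a valid
#' parameter set.
#'
#' Consumes the current RNG state; wrap in `set.seed()` (or use [run_psa()])
#' for reproducibility.
#'
#' @param params a `deprev_params` object.
#' @param max_tries rejection-sampling cap before erroring.
#' @return Named list of sampled point values.
#' @export
sample_parameters <- function(params, max_tries = 1000) {
  stopifnot(inherits(params, "deprev_params"))
  entries <- params$parameters[order(names(params$parameters))]
  for (i in seq_len(max_tries)) {
    draw <- lapply(names(entries), function(nm) {
      e <- entries[[nm]]
      if (e$family == "fixed") return(e$value)
      se <- resolved_se(e)
      switch(e$family,
        beta = {
          ab <- beta_from_mean_se(e$value, se, name = nm)
          stats::rbeta(1, ab$shape1, ab$shape2)
        },
        gamma = {
          gs <- gamma_from_mean_se(e$value, se, name = nm)
          stats::rgamma(1, shape = gs$shape, scale = gs$scale)
        },
        lognormal = {
          if (!is.na(e$ci_low) && !is.na(e$ci_high)) {
            ln <- lognormal_from_or_ci(e$value, e$ci_low, e$ci_high, name = nm)
          } else {
            ln <- list(meanlog = log(e$value), sdlog = se / e$value)
          }
          stats::rlnorm(1, ln$meanlog, ln$sdlog)
        }
      )
    })
    names(draw) <- names(entries)
    draw <- draw[.deprev_param_names]
    ok <- tryCatch({ validate_point(draw); TRUE }, error = function(e) FALSE)
    if (ok) return(draw)
  }
  stop("could not draw a valid parameter set in ", max_tries, " attempts")
}

#' Run the probabilistic sensitivity analysis
#'
#' Draws `n_sims` parameter sets with [sample_parameters()] and evaluates the
#' full decision model (all three arms, costs and QALYs) for each draw.
#'
#' @param params a `deprev_params` object.
#' @param n_sims number of simulations.
#' @param seed integer RNG seed; identical seeds give identical results.
#' @param wtp willingness to pay per QALY for the NMB summaries.
#' @param or_scale,half_cycle model options, see [deprev_model()].
#' @return An object of class `deprev_psa`: matrices `cost`, `qalys`, `cases`
#'   and `nmb` (`n_sims` rows, one column per arm), `cases_prevented`
#'   (per-draw, prevention arms vs TAU), plus the inputs and options.
#' @examples
#' psa <- run_psa(reference_parameters(), n_sims = 200, seed = 1)
#' summary(psa)
#' @export
run_psa <- function(params, n_sims = 10000, seed = 1, wtp = NULL,
                    or_scale = c("risk", "odds"), half_cycle = NULL) {
  stopifnot(inherits(params, "deprev_params"), n_sims >= 1)
  or_scale <- match.arg(or_scale)
  validate_parameters(params)
  point <- point_estimates(params)
  if (is.null(wtp)) wtp <- point$wtp
  if (is.null(half_cycle)) half_cycle <- isTRUE(point$half_cycle_correction)

  arms <- .deprev_arms
  cost <- qalys <- cases <- matrix(NA_real_, n_sims, length(arms),
                                   dimnames = list(NULL, arms))
  set.seed(seed)
  for (i in seq_len(n_sims)) {
    draw <- sample_parameters(params)
    for (a in arms) {
      ev <- evaluate_arm(draw, a, or_scale = or_scale, half_cycle = half_cycle)
      ec <- arm_economics(ev, draw, wtp = wtp, half_cycle = half_cycle)
      cost[i, a] <- ec$total_cost
      qalys[i, a] <- ec$total_qalys
      cases[i, a] <- ec$incident_cases
    }
  }
  structure(list(
    n_sims = n_sims,
    seed = seed,
    wtp = wtp,
    arms = arms,
    cost = cost,
    qalys = qalys,
    cases = cases,
    nmb = wtp * qalys - cost,
    cases_prevented = cases[, "tau"] - cases[, c("predictd_prevention",
                                                 "universal_prevention"),
                                             drop = FALSE],
    params = params,
    or_scale = or_scale,
    half_cycle = half_cycle
  ), class = "deprev_psa")
}

#' @export
print.deprev_psa <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %d simulations (seed %s)\n",
              x$n_sims, format(x$seed)))
  cat(sprintf("  mean cases prevented vs TAU: %.1f (risk algorithm + prevention), %.1f (universal)\n",
              mean(x$cases_prevented[, "predictd_prevention"]),
              mean(x$cases_prevented[, "universal_prevention"])))
  pr <- prob_optimal(x, x$wtp)
  cat(sprintf("  P(optimal at WTP GBP %s/QALY): %s\n",
              format(x$wtp, big.mark = ","),
              paste(sprintf("%s %.2f", names(pr), pr), collapse = ", ")))
  invisible(x)
}

#' Summarise a PSA
#'
#' @param object a `deprev_psa`.
#' @param probs percentile interval bounds.
#' @param ... unused.
#' @return A `data.frame` with, per arm, the PSA mean and percentile interval
#'   of total cost, QALYs, incident cases and NMB.
#' @export
summary.deprev_psa <- function(object, probs = c(0.025, 0.975), ...) {
  qi <- function(m) apply(m, 2, stats::quantile, probs = probs)
  out <- do.call(rbind, lapply(c("cost", "qalys", "cases", "nmb"), function(q) {
    m <- object[[q]]
    data.frame(
      quantity = q,
      arm = colnames(m),
      mean = colMeans(m),
      lower = qi(m)[1, ],
      upper = qi(m)[2, ],
      row.names = NULL, stringsAsFactors = FALSE
    )
  }))
  attr(out, "probs") <- probs
  out
}

# Probability each arm attains the highest NMB at a single WTP; exact ties
# split evenly between the tied arms.
prob_optimal <- function(psa, wtp) {
  nmb <- wtp * psa$qalys - psa$cost
  best <- nmb == matrixStats_rowMaxs(nmb)
  w <- best / rowSums(best)
  colMeans(w)
}

matrixStats_rowMaxs <- function(m) do.call(pmax, as.data.frame(m))

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value on a grid, the proportion of PSA draws
#' in which each arm attains the highest net monetary benefit (exact ties
#' split evenly), so the three probabilities sum to 1 at every grid point.
#'
#' @param psa a `deprev_psa` object.
#' @param wtp_grid willingness-to-pay grid, GBP/QALY.
#' @return A `data.frame` of class `deprev_ceac` with columns `wtp`, `arm`,
#'   `probability`.
#' @examples
#' psa <- run_psa(reference_parameters(), n_sims = 200, seed = 1)
#' head(ceac(psa))
#' @export
ceac <- function(psa, wtp_grid = seq(0, 50000, by = 1000)) {
  stopifnot(inherits(psa, "deprev_psa"), length(wtp_grid) >= 1)
  probs <- t(vapply(wtp_grid, function(w) prob_optimal(psa, w),
                    numeric(length(psa$arms))))
  out <- data.frame(
    wtp = rep(wtp_grid, times = length(psa$arms)),
    arm = rep(psa$arms, each = length(wtp_grid)),
    probability = as.vector(probs),
    stringsAsFactors = FALSE
  )
  class(out) <- c("deprev_ceac", "data.frame")
  out
}

#' Plot cost-effectiveness acceptability curves
#'
#' Base-graphics plot of the probability each arm is the optimal choice as a
#' function of the willingness to pay per QALY.
#'
#' @param x a `deprev_ceac` (or a `deprev_psa`, which is converted with the
#'   default grid).
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.deprev_ceac <- function(x, ...) {
  wide <- do.call(cbind, lapply(split(x$probability, x$arm), identity))
  wtp <- sort(unique(x$wtp))
  ord <- order(unique(x$wtp))
  graphics::matplot(wtp, wide[ord, , drop = FALSE], type = "l", lty = 1, lwd = 2,
                    xlab = "Willingness to pay per QALY (GBP)",
                    ylab = "Probability optimal", ylim = c(0, 1), ...)
  graphics::legend("right", legend = colnames(wide), lty = 1, lwd = 2,
                   col = seq_len(ncol(wide)), bty = "n")
  invisible(x)
}

#' @export
plot.deprev_psa <- function(x, ...) plot(ceac(x), ...)
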