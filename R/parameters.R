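# Parameter sets: each model input is one entry carrying a point estimate, an
# uncertainty family for the PSA (beta for probabilities/utilities, gamma for
# costs, log-normal for odds ratios, fixed for design constants), and
# provenance flags. The point estimates and the distributions live together so
# the "distribution mean equals the point estimate" invariant holds by
# construction.

.deprev_families <- c("beta", "gamma", "lognormal", "fixed")

.deprev_entry_fields <- c("value", "family", "se", "ci_low", "ci_high", "assumed", "source")

.deprev_param_names <- c(
  "cohort_size", "horizon_cycles", "annual_incidence", "recovery_prob_6m",
  "screening_threshold", "screening_sensitivity", "screening_specificity",
  "or_targeted", "or_universal",
  "utility_well", "utility_depressed", "utility_recovered",
  "annual_treatment_cost", "programme_cost_per_patient",
  "nurse_minutes_per_patient", "nurse_cost_per_hour", "training_cost",
  "universal_uptake", "wtp", "half_cycle_correction"
)

param_entry <- function(value, family = "fixed", se = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        assumed = FALSE, source = NA_character_) {
  list(value = value, family = family, se = se,
       ci_low = ci_low, ci_high = ci_high,
       assumed = assumed, source = source)
}

#' Construct a parameter set
#'
#' Low-level constructor for a `deprev_params` object from a named list of
#' parameter entries. Most users want [reference_parameters()] instead.
#'
#' @param entries named list; each element a list with fields `value`,
#'   `family` (one of beta, gamma, lognormal, fixed), optional `se` or
#'   `ci_low`/`ci_high`, logical `assumed`, and a free-text `source` note.
#' @param validate run [validate_parameters()] on the result.
#' @return An object of class `deprev_params`.
#' @export
parameter_set <- function(entries, validate = TRUE) {
  if (is.null(names(entries)) || any(!nzchar(names(entries))))
    stop("all parameter entries must be named")
  entries <- lapply(entries, function(e) {
    miss <- setdiff(.deprev_entry_fields, names(e))
    for (f in miss) e[[f]] <- switch(f,
      se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      assumed = FALSE, source = NA_character_,
      stop("entry lacks required field '", f, "'")
    )
    e[.deprev_entry_fields]
  })
  x <- structure(list(parameters = entries), class = "deprev_params")
  if (validate) validate_parameters(x)
  x
}

#' Reference parameter set for the depression-prevention model
#'
#' The canonical inputs: a cohort of 1000 general-practice attendees per arm,
#' 12-month (four quarterly cycle) horizon, 8.8% annual incidence of major
#' depression, risk-algorithm screening at the base threshold 0.133
#' (sensitivity 0.506, specificity 0.8), a targeted prevention-programme odds
#' ratio of 0.66, programme cost with mean GBP 100 (gamma, SE 50, spanning
#' roughly GBP 0–200), 15 nurse-minutes of screening administration per
#' patient plus GBP 2000 training, well-state utility 0.86, and a
#' willingness-to-pay threshold of GBP 20,000 per QALY.
#'
#' Inputs that the underlying evidence base does not report precisely are
#' marked `assumed = TRUE` in the entry (see the `source` notes and the
#' methods vignette): the six-month recovery probability (0.50), the depressed
#' and recovered utilities (0.58, 0.72), the weighted annual depression
#' treatment cost (GBP 400, with the SE-equals-mean convention), the nurse
#' hourly rate (GBP 42), the universal-programme odds ratio (0.90) and the
#' standard errors of several probabilities and utilities.
#'
#' @return A `deprev_params` object.
#' @examples
#' p <- reference_parameters()
#' point_estimates(p)$annual_incidence
#' @export
reference_parameters <- function() {
  parameter_set(list(
    cohort_size = param_entry(1000, "fixed",
      source = "1000 adults per treatment arm"),
    horizon_cycles = param_entry(4, "fixed",
      source = "12-month horizon in quarterly cycles"),
    annual_incidence = param_entry(0.088, "beta", se = 0.0084,
      source = "12-month incidence of major depression in primary care; SE assumed (binomial, n = 1131 development sample)"),
    recovery_prob_6m = param_entry(0.50, "beta", se = 0.05, assumed = TRUE,
      source = "assumed: 6-month probability of recovery from an episode"),
    screening_threshold = param_entry(0.133, "fixed",
      source = "base risk-score threshold"),
    screening_sensitivity = param_entry(0.506, "beta", se = 0.05,
      source = "sensitivity at threshold 0.133; SE assumed (binomial on incident cases)"),
    screening_specificity = param_entry(0.8, "beta", se = 0.013,
      source = "specificity at threshold 0.133; SE assumed (binomial on non-cases)"),
    or_targeted = param_entry(0.66, "lognormal", ci_low = 0.55, ci_high = 0.79,
      source = "pooled OR, targeted prevention programmes; CI assumed at the meta-analytic pooled precision"),
    or_universal = param_entry(0.90, "lognormal", ci_low = 0.60, ci_high = 1.35,
      assumed = TRUE,
      source = "assumed: OR for universal programmes, calibrated to ~8 of 88 expected cases prevented; wide CI (2 studies)"),
    utility_well = param_entry(0.86, "beta", se = 0.02,
      source = "general-population EQ-5D utility; SE assumed"),
    utility_depressed = param_entry(0.58, "beta", se = 0.05, assumed = TRUE,
      source = "assumed: utility in the depressed state (weighted average of UK trials)"),
    utility_recovered = param_entry(0.72, "beta", se = 0.05, assumed = TRUE,
      source = "assumed: utility after recovery within the year"),
    annual_treatment_cost = param_entry(400, "gamma", se = 400, assumed = TRUE,
      source = "assumed: weighted annual NHS cost of treating depression; SE set equal to the mean (unreported-SE convention)"),
    programme_cost_per_patient = param_entry(100, "gamma", se = 50,
      source = "prevention programme cost, mean GBP 100 over a GBP 0-200 range"),
    nurse_minutes_per_patient = param_entry(15, "fixed",
      source = "nurse time to administer the risk algorithm"),
    nurse_cost_per_hour = param_entry(42, "gamma", se = 42, assumed = TRUE,
      source = "assumed: GP-nurse unit cost per hour (PSSRU-style rate); SE set equal to the mean"),
    training_cost = param_entry(2000, "fixed",
      source = "training nurses to administer the risk algorithm for 1000 patients"),
    universal_uptake = param_entry(1.0, "fixed",
      source = "base case: all patients offered universal prevention access it"),
    wtp = param_entry(20000, "fixed",
      source = "willingness to pay per QALY"),
    half_cycle_correction = param_entry(FALSE, "fixed",
      source = "base case attributes full-cycle costs/disutility to transition cycles")
  ))
}

#' Point estimates of a parameter set
#'
#' @param x a `deprev_params` object.
#' @return Named list of parameter values (the distribution means).
#' @export
point_estimates <- function(x) {
  stopifnot(inherits(x, "deprev_params"))
  lapply(x$parameters, `[[`, "value")
}

#' Validate a parameter set
#'
#' Checks every entry's distribution family and moment feasibility, and the
#' joint invariants of the point estimates (probabilities, utilities and
#' uptake in \[0,1\]; costs non-negative; odds ratios positive; utility
#' ordering depressed <= recovered <= well; cohort and cycle counts at least
#' 1). Errors name the offending parameter.
#'
#' @param x a `deprev_params` object.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_parameters <- function(x) {
  stopifnot(inherits(x, "deprev_params"))
  entries <- x$parameters
  miss <- setdiff(.deprev_param_names, names(entries))
  if (length(miss)) stop("missing parameter(s): ", paste(miss, collapse = ", "))

  for (nm in names(entries)) {
    e <- entries[[nm]]
    if (!is.character(e$family) || !(e$family %in% .deprev_families))
      stop(sprintf("%s: unknown distribution family '%s'", nm, as.character(e$family)))
    if (nm == "half_cycle_correction") next
    if (!is.numeric(e$value) || length(e$value) != 1L || !is.finite(e$value))
      stop(sprintf("%s: value must be a single finite number", nm))
    se <- resolved_se(e)
    switch(e$family,
      beta = {
        if (e$value <= 0 || e$value >= 1)
          stop(sprintf("%s: beta family requires value in (0, 1)", nm))
        beta_from_mean_se(e$value, se, name = nm)
      },
      gamma = {
        if (e$value <= 0) stop(sprintf("%s: gamma family requires value > 0", nm))
        gamma_from_mean_se(e$value, se, name = nm)
      },
      lognormal = {
        if (e$value <= 0) stop(sprintf("%s: lognormal family requires value > 0", nm))
        if (is.na(e$ci_low) || is.na(e$ci_high)) {
          if (is.na(se)) stop(sprintf("%s: lognormal requires an se or a 95%% CI", nm))
        } else {
          lognormal_from_or_ci(e$value, e$ci_low, e$ci_high, name = nm)
        }
      },
      fixed = NULL
    )
  }
  validate_point(point_estimates(x))
  invisible(x)
}

# SE used for sampling; the unreported-SE convention sets se = mean.
resolved_se <- function(e) {
  if (!is.na(e$se)) return(e$se)
  if (e$family %in% c("beta", "gamma") &&
      (is.na(e$ci_low) || is.na(e$ci_high))) return(e$value)
  e$se
}

#' Validate a list of point-estimate values
#'
#' @param p named list of parameter values (as from [point_estimates()] or
#'   [sample_parameters()]).
#' @return `p`, invisibly, if valid; otherwise an error naming the parameter.
#' @export
validate_point <- function(p) {
  need <- setdiff(.deprev_param_names, names(p))
  if (length(need)) stop("missing parameter(s): ", paste(need, collapse = ", "))
  chk <- function(cond, nm, what) {
    if (!isTRUE(cond)) stop(sprintf("%s: %s (value = %s)", nm, what, format(p[[nm]])))
  }
  probs <- c("annual_incidence", "recovery_prob_6m", "screening_sensitivity",
             "screening_specificity", "utility_well", "utility_depressed",
             "utility_recovered", "universal_uptake")
  for (nm in probs) chk(p[[nm]] >= 0 && p[[nm]] <= 1, nm, "must lie in [0, 1]")
  chk(p$annual_incidence < 1, "annual_incidence", "must be < 1")
  costs <- c("annual_treatment_cost", "programme_cost_per_patient",
             "nurse_minutes_per_patient", "nurse_cost_per_hour",
             "training_cost", "wtp")
  for (nm in costs) chk(p[[nm]] >= 0, nm, "must be non-negative")
  for (nm in c("or_targeted", "or_universal")) chk(p[[nm]] > 0, nm, "must be > 0")
  chk(p$cohort_size >= 1, "cohort_size", "must be at least 1")
  chk(p$horizon_cycles >= 1, "horizon_cycles", "must be at least 1")
  chk(p$utility_depressed <= p$utility_recovered, "utility_depressed",
      "must not exceed utility_recovered")
  chk(p$utility_recovered <= p$utility_well, "utility_recovered",
      "must not exceed utility_well")
  chk(is.logical(p$half_cycle_correction), "half_cycle_correction",
      "must be logical")
  invisible(p)
}

#' Generate a random, valid parameter set
#'
#' Draws every model input from a documented plausible range (uniform on the
#' ranges below) and returns a fully valid `deprev_params` object. Intended as
#' the input generator for property-style tests of the model pipeline; it is
#' deterministic in `seed`.
#'
#' Ranges: incidence 0.02–0.20/year; sensitivity 0.3–0.95 and specificity
#' 0.6–0.95; six-month recovery 0.3–0.7; targeted OR 0.2–0.95 and universal OR
#' 0.4–1.1 (CIs at +/-25% on the log scale); utilities ordered by construction
#' within 0.35–0.95; treatment cost GBP 100–1000/year; programme cost GBP
#' 20–300; nurse rate GBP 25–60/h; training GBP 0–5000; uptake 0–1; WTP GBP
#' 10,000–50,000; cohort 100–5000; 4 cycles.
#'
#' @param seed integer RNG seed.
#' @return A `deprev_params` object.
#' @export
random_parameters <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  set.seed(seed)
  u_well <- runif(1, 0.80, 0.95)
  u_dep <- runif(1, 0.35, 0.65)
  u_rec <- runif(1, u_dep, u_well)
  or_t <- runif(1, 0.2, 0.95)
  or_u <- runif(1, 0.4, 1.1)
  pe <- function(m) {  # beta entry with a feasible, moderate SE
    param_entry(m, "beta", se = 0.5 * sqrt(m * (1 - m)) * runif(1, 0.1, 0.5))
  }
  parameter_set(list(
    cohort_size = param_entry(sample(100:5000, 1), "fixed"),
    horizon_cycles = param_entry(4, "fixed"),
    annual_incidence = pe(runif(1, 0.02, 0.20)),
    recovery_prob_6m = pe(runif(1, 0.3, 0.7)),
    screening_threshold = param_entry(runif(1, 0.05, 0.3), "fixed"),
    screening_sensitivity = pe(runif(1, 0.3, 0.95)),
    screening_specificity = pe(runif(1, 0.6, 0.95)),
    or_targeted = param_entry(or_t, "lognormal",
                              ci_low = or_t * 0.75, ci_high = or_t / 0.75),
    or_universal = param_entry(or_u, "lognormal",
                               ci_low = or_u * 0.75, ci_high = or_u / 0.75),
    utility_well = pe(u_well),
    utility_depressed = pe(u_dep),
    utility_recovered = pe(u_rec),
    annual_treatment_cost = param_entry(runif(1, 100, 1000), "gamma",
                                        se = runif(1, 50, 500)),
    programme_cost_per_patient = param_entry(runif(1, 20, 300), "gamma",
                                             se = runif(1, 10, 100)),
    nurse_minutes_per_patient = param_entry(runif(1, 5, 30), "fixed"),
    nurse_cost_per_hour = param_entry(runif(1, 25, 60), "fixed"),
    training_cost = param_entry(runif(1, 0, 5000), "fixed"),
    universal_uptake = param_entry(runif(1), "fixed"),
    wtp = param_entry(round(runif(1, 10000, 50000)), "fixed"),
    half_cycle_correction = param_entry(runif(1) < 0.5, "fixed")
  ))
}

#' Read / write a parameter set as JSON
#'
#' `write_parameters()` serializes a `deprev_params` object to a JSON document
#' (one object per parameter with fields `value`, `family`, `se`, `ci_low`,
#' `ci_high`, `assumed`, `source`; absent fields are omitted).
#' `read_parameters()` parses and validates it, reporting the offending
#' parameter name on failure. The round trip is the identity.
#'
#' @param x a `deprev_params` object.
#' @param path file path.
#' @return `read_parameters()` returns a validated `deprev_params` object;
#'   `write_parameters()` returns `path` invisibly.
#' @export
write_parameters <- function(x, path) {
  stopifnot(inherits(x, "deprev_params"))
  out <- lapply(x$parameters, function(e) e[!vapply(e, function(v) is.na(v)[1], logical(1))])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!length(raw) || is.null(names(raw))) stop("parameter file holds no named parameters")
  entries <- lapply(names(raw), function(nm) {
    e <- raw[[nm]]
    unknown <- setdiff(names(e), .deprev_entry_fields)
    if (length(unknown))
      stop(sprintf("%s: unknown field(s) %s", nm, paste(unknown, collapse = ", ")))
    if (is.null(e$value)) stop(sprintf("%s: missing field 'value'", nm))
    if (is.null(e$family)) stop(sprintf("%s: missing field 'family'", nm))
    param_entry(
      value = if (is.logical(e$value)) e$value else as.numeric(e$value),
      family = e$family,
      se = if (is.null(e$se)) NA_real_ else as.numeric(e$se),
      ci_low = if (is.null(e$ci_low)) NA_real_ else as.numeric(e$ci_low),
      ci_high = if (is.null(e$ci_high)) NA_real_ else as.numeric(e$ci_high),
      assumed = isTRUE(e$assumed),
      source = if (is.null(e$source)) NA_character_ else e$source
    )
  })
  names(entries) <- names(raw)
  parameter_set(entries)
}

#' Override parameters in a set
#'
#' Returns a copy of `x` with the named parameters replaced. A bare numeric
#' (or logical) sets the point value and leaves the family untouched; for
#' log-normal entries the CI is recentred on the new value, preserving its
#' log-scale width. A list may set any of `value`, `family`, `se`, `ci_low`,
#' `ci_high`.
#'
#' @param x a `deprev_params` object.
#' @param ... named overrides, e.g. `or_targeted = 0.6` or
#'   `or_targeted = list(value = 0.6, ci_low = 0.3, ci_high = 1.2)`.
#' @return A validated `deprev_params` object.
#' @examples
#' p <- set_parameters(reference_parameters(), screening_sensitivity = 0.458,
#'                     screening_specificity = 0.85)
#' @export
set_parameters <- function(x, ...) {
  stopifnot(inherits(x, "deprev_params"))
  dots <- list(...)
  if (!length(dots)) return(x)
  if (is.null(names(dots)) || any(!nzchar(names(dots))))
    stop("all overrides must be named")
  for (nm in names(dots)) {
    if (!nm %in% names(x$parameters)) stop("unknown parameter: ", nm)
    e <- x$parameters[[nm]]
    ov <- dots[[nm]]
    if (is.list(ov)) {
      bad <- setdiff(names(ov), .deprev_entry_fields)
      if (length(bad)) stop(sprintf("%s: unknown field(s) %s", nm, paste(bad, collapse = ", ")))
      e[names(ov)] <- ov
    } else {
      if (e$family == "lognormal" && !is.na(e$ci_low) && !is.na(e$ci_high)) {
        ratio <- ov / e$value          # keep the log-scale CI width
        e$ci_low <- e$ci_low * ratio
        e$ci_high <- e$ci_high * ratio
      }
      e$value <- ov
    }
    x$parameters[[nm]] <- e
  }
  validate_parameters(x)
  x
}

#' Fix all distributions at their point estimates
#'
#' Utility for degenerate-PSA checks: returns a copy of `x` with every
#' family set to `fixed`, so that sampled draws equal the point estimates.
#'
#' @param x a `deprev_params` object.
#' @return A `deprev_params` object with all families `fixed`.
#' @export
fix_all_parameters <- function(x) {
  stopifnot(inherits(x, "deprev_params"))
  x$parameters <- lapply(x$parameters, function(e) {
    e$family <- "fixed"
    e
  })
  x
}

#' @export
print.deprev_params <- function(x, ...) {
  p <- point_estimates(x)
  fam <- vapply(x$parameters, `[[`, character(1), "family")
  ass <- vapply(x$parameters, `[[`, logical(1), "assumed")
  cat("Depression-prevention model parameter set\n")
  cat(sprintf("  %d parameters (%d uncertain, %d flagged as assumed)\n",
              length(p), sum(fam != "fixed"), sum(ass)))
  df <- data.frame(
    value = vapply(p, function(v) if (is.logical(v)) as.numeric(v) else v, numeric(1)),
    family = fam,
    assumed = ifelse(ass, "yes", ""),
    row.names = names(p)
  )
  print(df, digits = 4)
  invisible(x)
}
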