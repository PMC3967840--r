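test_that("reference fixture carries the canonical inputs and validates", {
  p <- reference_parameters()
  expect_silent(validate_parameters(p))
  pt <- point_estimates(p)
  expect_equal(pt$cohort_size, 1000)
  expect_equal(pt$horizon_cycles, 4)
  expect_equal(pt$annual_incidence, 0.088)
  expect_equal(pt$screening_threshold, 0.133)
  expect_equal(pt$screening_sensitivity, 0.506)
  expect_equal(pt$screening_specificity, 0.8)
  expect_equal(pt$or_targeted, 0.66)
  expect_equal(pt$programme_cost_per_patient, 100)
  expect_equal(p$parameters$programme_cost_per_patient$se, 50)
  expect_equal(pt$nurse_minutes_per_patient, 15)
  expect_equal(pt$training_cost, 2000)
  expect_equal(pt$utility_well, 0.86)
  expect_equal(pt$universal_uptake, 1.0)
  expect_equal(pt$wtp, 20000)

  # distribution families follow the probabilities-beta / costs-gamma /
  # odds-ratios-lognormal convention
  fam <- vapply(p$parameters, `[[`, character(1), "family")
  expect_equal(unname(fam[c("annual_incidence", "utility_well", "recovery_prob_6m")]),
               rep("beta", 3))
  expect_equal(unname(fam[c("annual_treatment_cost", "programme_cost_per_patient")]),
               rep("gamma", 2))
  expect_equal(unname(fam[c("or_targeted", "or_universal")]), rep("lognormal", 2))

  # values the evidence base does not print are flagged as assumptions
  assumed <- names(which(vapply(p$parameters, `[[`, logical(1), "assumed")))
  expect_true(all(c("recovery_prob_6m", "utility_depressed", "utility_recovered",
                    "annual_treatment_cost", "nurse_cost_per_hour",
                    "or_universal") %in% assumed))
})

test_that("random parameter sets are deterministic in the seed and always valid", {
  a <- random_parameters(1)
  b <- random_parameters(1)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_parameters(a, f1); write_parameters(b, f2)
  expect_identical(readLines(f1), readLines(f2))  # bitwise-identical serialization
  expect_false(identical(readLines(f1),
                         {write_parameters(random_parameters(2), f2); readLines(f2)}))
  unlink(c(f1, f2))

  # fuzz: every generated set passes the validator
  for (seed in 1:1000) {
    expect_silent(validate_parameters(random_parameters(seed)))
  }
})

test_that("JSON round trip is the identity and errors name the parameter", {
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path), add = TRUE)

  ref <- reference_parameters()
  write_parameters(ref, path)
  expect_equal(read_parameters(path), ref)

  for (seed in c(3, 77)) {
    rp <- random_parameters(seed)
    write_parameters(rp, path)
    expect_equal(read_parameters(path), rp)
  }

  # out-of-range value is reported with the offending name
  bad <- ref
  bad$parameters$screening_sensitivity$value <- 1.2
  write_parameters(bad, path)
  expect_error(read_parameters(path), "screening_sensitivity")

  # unknown distribution family
  bad <- ref
  bad$parameters$or_targeted$family <- "weibull"
  write_parameters(bad, path)
  expect_error(read_parameters(path), "or_targeted.*weibull")

  # missing field
  txt <- jsonlite::read_json(path)
  txt$or_targeted <- list(family = "lognormal")
  jsonlite::write_json(txt, path, auto_unbox = TRUE)
  expect_error(read_parameters(path), "or_targeted.*value")
})

test_that("omitted standard errors fall back to the SE-equals-mean convention", {
  p <- reference_parameters()
  p$parameters$annual_incidence$se <- NA_real_
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path), add = TRUE)
  write_parameters(p, path)
  loaded <- read_parameters(path)  # loads, with the fallback applied at sampling
  e <- loaded$parameters$annual_incidence
  expect_true(is.na(e$se))
  expect_equal(deprev:::resolved_se(e), e$value)
  # the fallback SE is feasible for a mean below 1/2, so sampling works
  set.seed(1)
  expect_silent(validate_point(sample_parameters(loaded)))
  # ... but is rejected, naming the parameter, where it breaks moment feasibility
  q <- reference_parameters()
  q$parameters$utility_well$se <- NA_real_
  expect_error(validate_parameters(q), "utility_well.*infeasible")
})

test_that("parameter overrides validate, recentre CIs, and undo cleanly", {
  p <- reference_parameters()
  q <- set_parameters(p, screening_sensitivity = 0.458, screening_specificity = 0.85)
  expect_equal(point_estimates(q)$screening_sensitivity, 0.458)
  expect_error(set_parameters(p, not_a_parameter = 1), "unknown parameter")
  expect_error(set_parameters(p, screening_sensitivity = 1.7), "screening_sensitivity")

  # scalar override of a lognormal entry keeps the CI's log-scale width
  r <- set_parameters(p, or_targeted = 0.5)
  e <- r$parameters$or_targeted
  ref_e <- p$parameters$or_targeted
  expect_equal(e$value, 0.5)
  expect_equal(log(e$ci_high) - log(e$ci_low),
               log(ref_e$ci_high) - log(ref_e$ci_low))

  # applying then removing an override restores the original set
  back <- set_parameters(r, or_targeted = 0.66)
  expect_equal(back, p)

  # list override can replace the whole uncertainty description
  s <- set_parameters(p, or_targeted = list(value = 0.6, ci_low = 0.3, ci_high = 1.2))
  expect_equal(s$parameters$or_targeted$ci_low, 0.3)
})
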