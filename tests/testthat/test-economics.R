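test_that("screening and treatment-mix costs follow their closed forms", {
  expect_equal(screening_cost(0, 15, 42, 2000), 2000)
  expect_equal(screening_cost(1000, 15, 42, 2000), 12500)
  expect_equal(screening_cost(2000, 15, 42, 0), 2 * screening_cost(1000, 15, 42, 0))

  expect_equal(weighted_treatment_cost(1, 400), 400)
  expect_equal(weighted_treatment_cost(c(0.5, 0.25), c(100, 400)), 150)
  expect_equal(weighted_treatment_cost(numeric(0), numeric(0)), 0)
  expect_error(weighted_treatment_cost(c(0.7, 0.6), c(100, 100)), "sum above 1")
  expect_error(weighted_treatment_cost(0.5, c(100, 200)), "same length")
})

test_that("arm economics: degenerate cases and the NMB identity", {
  pt <- point_estimates(reference_parameters())

  # no disease: no cost, full-health QALYs
  pt0 <- pt; pt0$annual_incidence <- 0
  ev <- evaluate_arm(pt0, "tau")
  ec <- arm_economics(ev, pt0)
  expect_equal(ec$total_cost, 0)
  expect_equal(ec$total_qalys, 1000 * 0.86)
  expect_equal(ec$per_patient_nmb, 20000 * 0.86)

  # NMB identity holds exactly for every arm, parameter set and WTP
  for (seed in c(5, 21, 404)) {
    draw <- point_estimates(random_parameters(seed))
    for (arm in c("tau", "predictd_prevention", "universal_prevention")) {
      for (wtp in c(0, 13000, 30000)) {
        r <- arm_economics(evaluate_arm(draw, arm), draw, wtp = wtp)
        expect_identical(r$nmb, wtp * r$total_qalys - r$total_cost)
        # per-patient NMB is bounded by a year of perfect-reference health
        expect_lt(r$per_patient_nmb, wtp * draw$utility_well + 1e-9)
      }
    }
  }
})

test_that("QALYs fall as incident cases rise, holding utilities fixed", {
  pt <- point_estimates(reference_parameters())
  res <- vapply(c(0.02, 0.088, 0.2, 0.4), function(inc) {
    p <- pt; p$annual_incidence <- inc
    ec <- arm_economics(evaluate_arm(p, "tau"), p)
    c(ec$incident_cases, ec$total_qalys)
  }, numeric(2))
  expect_true(all(diff(res[1, ]) > 0))
  expect_true(all(diff(res[2, ]) < 0))
})

test_that("half-cycle correction lowers treatment cost and raises QALYs", {
  pt <- point_estimates(reference_parameters())
  for (arm in c("tau", "predictd_prevention", "universal_prevention")) {
    ev <- evaluate_arm(pt, arm, half_cycle = FALSE)
    base <- arm_economics(ev, pt, half_cycle = FALSE)
    corr <- arm_economics(ev, pt, half_cycle = TRUE)
    expect_lt(corr$cost_treatment, base$cost_treatment)
    expect_gt(corr$total_qalys, base$total_qalys)
    expect_equal(corr$cost_programme, base$cost_programme)
    expect_equal(corr$cost_screening, base$cost_screening)
  }
})

test_that("incremental analysis applies the strong-dominance definition", {
  # identical arms: zero increments, no dominance
  same <- lapply(c("tau", "predictd_prevention", "universal_prevention"),
                 fake_arm_result, cost = 100, qalys = 50)
  tab <- incremental_analysis(same)
  expect_equal(tab$inc_cost, rep(0, 3))
  expect_equal(tab$inc_qalys, rep(0, 3))
  expect_false(any(tab$strongly_dominated))

  # B costs more and yields fewer QALYs than A: B strongly dominated
  mixed <- list(fake_arm_result("tau", 15, 4.5),
                fake_arm_result("predictd_prevention", 10, 5),
                fake_arm_result("universal_prevention", 20, 4))
  tab2 <- incremental_analysis(mixed)
  expect_equal(tab2$strongly_dominated, c(TRUE, FALSE, TRUE))
  expect_equal(tab2$arm[tab2$optimal], "predictd_prevention")

  expect_error(incremental_analysis(mixed[1:2]), "missing")
})

test_that("the fitted model exposes the standard S3 surface", {
  fit <- deprev_model()
  expect_s3_class(fit, "deprev_model")
  expect_output(print(fit), "cases prevented")
  sm <- summary(fit)
  expect_s3_class(sm, "data.frame")
  expect_equal(nrow(sm), 3)
  expect_equal(sm$cost_screening[sm$arm == "predictd_prevention"], 12500)
  expect_equal(sm$cost_programme[sm$arm == "universal_prevention"], 100000)
  cf <- coef(fit)
  expect_equal(unname(cf["annual_incidence"]), 0.088)

  # tidy trajectory export: one row per arm/group/cycle/state
  df <- as.data.frame(fit)
  expect_equal(names(df), c("arm", "group", "cycle", "state", "expected_count"))
  expect_equal(sum(df$expected_count[df$cycle == 4 & df$arm == "tau"]), 1000)
  # four groups across the three arms: 1 (tau) + 2 (targeted) + 1 (universal)
  expect_equal(nrow(df), 4 * 5 * 3)

  # simulate() is the PSA
  ps <- simulate(fit, nsim = 5, seed = 3)
  expect_s3_class(ps, "deprev_psa")
  expect_equal(ps$n_sims, 5)
})
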