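test_that("screening stratification reproduces the expected 2x2 split", {
  s <- stratify_cohort(1000, 0.088, 0.506, 0.8)
  expect_equal(s$tp, 1000 * 0.088 * 0.506)          # 44.528
  expect_equal(s$fn, 1000 * 0.088 * 0.494)
  expect_equal(s$fp, 1000 * 0.912 * 0.2)            # 182.4
  expect_equal(s$tn, 1000 * 0.912 * 0.8)
  expect_equal(s$tp + s$fp + s$tn + s$fn, 1000)
  expect_equal(s$high_risk_baseline_12m, 44.528 / (44.528 + 182.4))
  expect_equal(round(s$high_risk_baseline_12m, 4), 0.1962)
  expect_equal(s$low_risk_baseline_12m, s$fn / (s$tn + s$fn))

  perfect <- stratify_cohort(1000, 0.088, 1, 1)
  expect_equal(perfect$fp, 0)
  expect_equal(perfect$fn, 0)
  expect_equal(perfect$high_risk_baseline_12m, 1)
  expect_equal(perfect$low_risk_baseline_12m, 0)
})

test_that("cycle probabilities honour both effect-translation conventions", {
  # no effect: both scales collapse to the plain decomposition
  base_q <- rescale_probability(0.088, 12, 3)
  expect_equal(cycle_probability(0.088, or = 1, or_scale = "risk"), base_q)
  expect_equal(cycle_probability(0.088, or = 1, or_scale = "odds"), base_q)
  expect_equal(cycle_probability(0.088, or = 0.66, uptake = 0), base_q)

  # odds-scale route: apply_odds_ratio then decompose
  p12 <- (0.66 * 0.088 / 0.912) / (1 + 0.66 * 0.088 / 0.912)
  expect_equal(round(p12, 4), 0.0599)
  q <- cycle_probability(0.088, or = 0.66, or_scale = "odds")
  expect_equal(q, 1 - (1 - p12)^(1 / 4))
  expect_equal(round(q, 5), 0.01532)

  # risk-scale route: multiplicative on the baseline risk
  expect_equal(cycle_probability(0.088, or = 0.66, or_scale = "risk"),
               1 - (1 - 0.088 * 0.66)^(1 / 4))

  # uptake mixes treated and untreated 12-month risks linearly
  full <- 1 - (1 - cycle_probability(0.088, 0.66, 1))^4
  none <- 0.088
  half <- 1 - (1 - cycle_probability(0.088, 0.66, 0.5))^4
  expect_equal(half, (full + none) / 2)
})

test_that("Markov engine conserves the cohort and accumulates cases correctly", {
  # zero incidence: nothing moves
  t0 <- run_markov(500, 0, 0.3, cycles = 4)
  expect_equal(t0$occupancy[, "no_major_depression"], rep(500, 5),
               ignore_attr = TRUE)
  expect_equal(t0$cumulative_incident_cases, rep(0, 4))

  # compounding identity: quarterly decomposition of 8.8%/year over four
  # cycles yields 88 expected cases per 1000
  q <- rescale_probability(0.088, 12, 3)
  tr <- run_markov(1000, q, rescale_probability(0.5, 6, 3), cycles = 4)
  expect_equal(tr$cumulative_incident_cases[4], 88, tolerance = 1e-9)

  # conservation, non-negativity, monotone absorbing state, monotone cases
  set.seed(11)
  for (i in 1:25) {
    n <- runif(1, 10, 5000)
    tt <- run_markov(n, runif(1, 0, 0.4), runif(1, 0, 0.8),
                     cycles = sample(1:8, 1))
    expect_equal(rowSums(tt$occupancy), rep(n, tt$cycles + 1),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_true(all(tt$occupancy >= 0))
    expect_true(all(diff(tt$occupancy[, "recovered"]) >= 0))
    expect_true(all(diff(tt$cumulative_incident_cases) >= -1e-12))
  }
})

test_that("cohort engine agrees with an individual-level microsimulation", {
  n <- 1e5
  q_inc <- rescale_probability(0.088, 12, 3)
  q_rec <- rescale_probability(0.5, 6, 3)
  cohort <- run_markov(1, q_inc, q_rec, cycles = 4)  # per-patient fractions
  micro <- microsim_occupancy(n, q_inc, q_rec, cycles = 4, seed = 99)
  for (t in 2:5) {
    for (s in 1:3) {
      p <- cohort$occupancy[t, s]
      se <- sqrt(n * p * (1 - p))
      expect_lt(abs(micro[t, s] - n * p), max(3 * se, 1e-9))
    }
  }
})

test_that("arm evaluation matches the decision tree's structure", {
  pt <- point_estimates(reference_parameters())

  # no treatment effect: targeted arm equals TAU in case counts
  pt1 <- pt; pt1$or_targeted <- 1
  tau <- evaluate_arm(pt1, "tau")
  pred <- evaluate_arm(pt1, "predictd_prevention")
  expect_equal(pred$incident_cases, tau$incident_cases, tolerance = 1e-9)

  # reference fixture: ~15 cases prevented by the targeted arm
  prevented <- evaluate_arm(pt, "tau")$incident_cases -
    evaluate_arm(pt, "predictd_prevention")$incident_cases
  expect_equal(prevented, 1000 * 0.088 * 0.506 * (1 - 0.66))
  expect_equal(round(prevented), 15)

  # a useless screen (Se = 0) sends every case to the untreated group
  pt0 <- pt; pt0$screening_sensitivity <- 0
  prev0 <- evaluate_arm(pt0, "tau")$incident_cases -
    evaluate_arm(pt0, "predictd_prevention")$incident_cases
  expect_equal(prev0, 0, tolerance = 1e-9)

  # a perfect screen with a perfectly effective programme prevents every case
  ptp <- pt
  ptp$screening_sensitivity <- 1; ptp$screening_specificity <- 1
  ptp$or_targeted <- 1e-12
  prevp <- evaluate_arm(ptp, "tau")$incident_cases -
    evaluate_arm(ptp, "predictd_prevention")$incident_cases
  expect_equal(prevp, 1000 * 0.088, tolerance = 1e-6)

  # universal arm at zero uptake has TAU's dynamics and no recipients
  ptu <- pt; ptu$universal_uptake <- 0
  uni <- evaluate_arm(ptu, "universal_prevention")
  expect_equal(uni$incident_cases, evaluate_arm(ptu, "tau")$incident_cases)
  expect_equal(uni$programme_recipients, 0)
})

test_that("cases prevented are monotone in effectiveness and sensitivity", {
  pt <- point_estimates(reference_parameters())
  prevented <- function(or, se, scale) {
    p <- pt; p$or_targeted <- or; p$screening_sensitivity <- se
    evaluate_arm(p, "tau", or_scale = scale)$incident_cases -
      evaluate_arm(p, "predictd_prevention", or_scale = scale)$incident_cases
  }
  for (scale in c("risk", "odds")) {
    by_or <- vapply(seq(0.1, 1, by = 0.1), prevented, numeric(1),
                    se = 0.506, scale = scale)
    expect_true(all(diff(by_or) <= 1e-12))
    by_se <- vapply(seq(0.1, 1, by = 0.1), function(s)
      prevented(0.66, s, scale), numeric(1))
    expect_true(all(diff(by_se) >= -1e-12))
  }
})
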