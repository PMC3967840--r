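# Shared helpers for the test suite.

# Individual-level microsimulation of the three-state process: an independent
# oracle for the expected-value cohort engine. States: 1 well, 2 depressed,
# 3 recovered (absorbing). Returns occupancy counts by cycle.
microsim_occupancy <- function(n, q_incidence, q_recovery, cycles, seed) {
  set.seed(seed)
  state <- rep(1L, n)
  occ <- matrix(0, nrow = cycles + 1, ncol = 3,
                dimnames = list(cycle = 0:cycles,
                                state = c("no_major_depression", "depressed", "recovered")))
  occ[1, 1] <- n
  for (t in seq_len(cycles)) {
    onset <- state == 1L & stats::runif(n) < q_incidence
    recov <- state == 2L & stats::runif(n) < q_recovery
    state[recov] <- 3L
    state[onset] <- 2L
    occ[t + 1, ] <- tabulate(state, nbins = 3L)
  }
  occ
}

# Reference set with every distribution collapsed to its point estimate:
# makes PSA runs deterministic for exact-equality checks.
fixed_reference <- function() fix_all_parameters(reference_parameters())

# A synthetic arm result for dominance-logic tests.
fake_arm_result <- function(arm, cost, qalys, cases = 0, wtp = 20000) {
  structure(list(
    arm = arm, cost_screening = 0, cost_programme = 0, cost_treatment = cost,
    total_cost = cost, total_qalys = qalys, incident_cases = cases,
    wtp = wtp, nmb = wtp * qalys - cost, per_patient_nmb = NA_real_
  ), class = "deprev_arm_result")
}
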