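---
title: "A decision-analytic model of depression prevention in primary care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision-analytic model of depression prevention in primary care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deprev)
```

## The decision problem

Major depression is common, costly and — with a validated risk algorithm —
partly predictable among general-practice attendees. `deprev` models, over a
12-month horizon and from an NHS cost perspective, three strategies for a
cohort of 1000 non-depressed adults per arm:

* **Risk algorithm plus prevention** (`predictd_prevention`): a practice
  nurse administers a depression risk score to every patient; those above
  the score threshold are offered a low-intensity prevention programme
  (bibliotherapy, computerised CBT, group therapy).
* **Universal prevention** (`universal_prevention`): everyone is offered the
  programme, with no risk assessment.
* **Treatment as usual** (`tau`): no screening, no prevention; incident
  cases receive usual GP care.

The model is a decision tree feeding a Markov cohort model, evaluated
deterministically and by probabilistic sensitivity analysis (PSA), and
summarised with net monetary benefit (NMB) and cost-effectiveness
acceptability curves (CEACs).

## Model structure

**Decision tree.** Screening splits the cohort by the joint distribution of
true disease destiny (12-month incidence $\pi$) and test result (sensitivity
$Se$, specificity $Sp$): $tp = n\pi Se$, $fn = n\pi(1-Se)$,
$fp = n(1-\pi)(1-Sp)$, $tn = n(1-\pi)Sp$. Screen-positives carry the
PPV-implied baseline risk $tp/(tp+fp)$; screen-negatives carry
$fn/(tn+fn)$. False positives matter: they receive (and cost) the programme
without being destined for depression.

**Markov model.** Three states — *no major depression*, *depressed*,
*recovered* — with quarterly cycles over 12 months (four cycles). Everyone
starts well; per cycle a group-specific probability moves well patients into
depression, and a recovery probability moves depressed patients (after at
least one full cycle depressed) into the absorbing recovered state. There is
no relapse arrow and no death state over this short horizon. The cohort is
tracked in expected fractional patients; counts are rounded only for
reporting.

**Time rescaling.** Probabilities quoted over 12 or 6 months are converted
to quarterly transition probabilities through the constant-rate pair
$r = -\ln(1-p)/t$ and $p = 1-e^{-rt}$. This makes the decomposition exact:
an annual incidence of 8.8% compounds back to exactly 88 expected cases per
1000 over four cycles.

**Treatment effect.** The prevention programme's effect is an odds ratio
(OR) against treatment as usual. Two conventions translate it into the
screen-positive group's absolute risk, exposed as `or_scale` in
`deprev_model()`, `cycle_probability()` and downstream:

* `"risk"` (default): the treated 12-month risk is $p_0 \cdot \mathrm{OR}$,
  i.e. the OR is applied multiplicatively as if it were a risk ratio;
* `"odds"`: $p_1 = \mathrm{OR}\,\omega/(1+\mathrm{OR}\,\omega)$ with
  $\omega = p_0/(1-p_0)$ (the Briggs-style odds conversion, available as
  `apply_odds_ratio()`).

For rare outcomes the two coincide; at the screen-positive baseline risk of
about 0.20 they do not (treated risk 0.129 vs 0.139 at OR 0.66). We default
to the risk-scale convention because it is the arithmetic under which this
decision problem's published case counts — about 15, 14 and 11 cases
prevented per 1000 at the three score thresholds, 39 under interpersonal
therapy, 18 under the GP-only pooled OR and 8 in the universal arm — are
reproduced; the odds-scale route yields systematically fewer prevented cases
(13.0 at the base threshold). Users preferring the strict odds conversion
set `or_scale = "odds"`. Uptake below 1 mixes treated and untreated risk
linearly before the quarterly decomposition, and the effect is applied to
the 12-month risk first, then decomposed (applying it per cycle instead
changes the base-case prevented count by under one case).

**Economics.** No discounting over the 12-month horizon. Annual costs and
utilities are divided by four so each cycle carries three months' worth.
Per arm:

* *screening cost* (targeted arm only): $n \times \text{minutes}/60 \times
  \text{hourly rate} + \text{training}$;
* *programme cost*: recipients × per-patient cost, where recipients are the
  screen-positives (targeted), the uptake fraction of the cohort
  (universal; the cost scales with uptake, a documented switch in the sense
  that zero uptake incurs zero cost), or nobody (TAU);
* *treatment cost*: depressed person-cycles × annual treatment cost / 4 —
  patients are costed for each full quarter spent depressed, and the
  recovered state costs nothing;
* *QALYs*: per cycle, state occupancy × state utility / 4, attributing the
  transition cycle to the destination state.

NMB is $\lambda \cdot \text{QALYs} - \text{cost}$ at willingness to pay
$\lambda$ (default £20,000/QALY). An arm is *strongly dominated* when some
other arm has strictly lower cost and strictly higher QALYs.

**Half-cycle correction** (`half_cycle = TRUE`, or the
`half_cycle_correction` parameter): patients entering depression in a cycle
spend half of that cycle with depression's costs and disutility and half
with the well state's, which strictly lowers treatment cost and raises
QALYs in every draw. `half_cycle_comparison()` evaluates both accountings on
identical draws.

## Parameters and their provenance

`reference_parameters()` returns the canonical input set; printing it shows
value, family and an `assumed` flag per parameter. Probabilities and
utilities are beta-distributed (method-of-moments from mean and SE), costs
gamma, odds ratios log-normal with the log-SD taken from a 95% CI where one
exists. Where an SE is unreported the convention SE = mean is applied (the
treatment cost and nurse rate use it); `read_parameters()` applies the same
fallback to files that omit an SE.

Key values: cohort 1000/arm; annual incidence 8.8% (SE 0.0084, the binomial
SE of the development sample); thresholds 0.133/0.154/0.183 with
sensitivity 0.506/0.458/0.373 and specificity 0.8/0.85/0.9; targeted OR
0.66, with an assumed 95% CI of 0.55–0.79 obtained by transferring the
log-scale precision of the source meta-analysis's pooled effect; universal
OR 0.90 (assumed; calibrated so the universal arm prevents roughly 8 of the
88 expected cases) with a deliberately wide CI 0.60–1.35 (it rests on two
studies); programme cost mean £100, SE £50 (placing ~95% of the gamma mass
under roughly £200); screening administration 15 nurse-minutes at £42/h
plus £2000 training; utilities 0.86 well / 0.72 recovered / 0.58 depressed
(the latter two assumed from UK trial averages, SE 0.05); six-month
recovery probability 0.50 (assumed); annual treatment cost £400 (assumed
weighted average across medication, psychological therapy, secondary care
and no treatment — `weighted_treatment_cost()` computes such averages);
uptake 1 in the universal arm; WTP £20,000/QALY.

Every `assumed = TRUE` value is a calibration choice, not an evidence-based
fact; serialized files carry the flag and a source note so downstream users
can see provenance at a glance.

## Probabilistic sensitivity analysis

`run_psa()` (or `simulate()` on a fitted model) draws each uncertain
parameter from its family and re-evaluates all three arms per draw.
Numerical conventions:

* one shared RNG stream, parameters drawn in alphabetical name order, so a
  seed pins the full analysis across refactors that reorder code;
* draws violating the joint invariants (e.g. a sampled recovered utility
  exceeding the sampled well utility, roughly 1 draw in 200) are rejected
  and redrawn, so every evaluated draw is a valid parameter set;
* CEAC ties are split evenly among the tied arms, so probabilities sum to 1
  at every WTP by construction;
* the default 10,000 simulations match standard practice; the test suite
  runs at 200–1000 draws, which bounds the Monte-Carlo SE of mean prevented
  cases near 0.1 cases and keeps the suite fast.

## Scenario and threshold analyses

`scenario_presets()` ships the standard variants (GP-only OR 0.6, CI
0.3–1.2; interpersonal therapy OR 0.13, CI 0.04–0.42; non-IP OR 0.75, CI
0.58–0.98; the two higher thresholds). `run_scenario()` applies overrides on
top of the reference set and reruns the whole pipeline.

`max_affordable_cost()` answers "how much may the programme cost, per
patient, before the targeted arm stops being the best choice at £20,000 per
QALY?" It holds the OR fixed, draws the remaining parameters, and finds the
root of the mean NMB gap by bisection on a £−500 to £1000 bracket. Because
the NMB gap is exactly linear in the programme cost for a fixed set of
draws, a final secant step sharpens the bisection root to machine
precision; a bracket endpoint of the wrong sign is reported as infeasible
(−∞) or unbounded (+∞). A negative root — which occurs as the OR approaches
1 — means no positive price makes the programme cost-effective.

`uptake_sweep()` varies the proportion of patients accessing the universal
programme over a grid with common random numbers across uptake values,
reporting the probability each arm is optimal and the largest uptake at
which universal prevention overtakes the targeted arm. Under the reference
fixture with our assumed SEs that crossover does not occur — the universal
arm's advantage would rest on uncertainty magnitudes the evidence base does
not pin down — so the function reports `NA` and the sweep serves as a
robustness statement for the targeted strategy.

## What the synthetic parameter generator does and does not emulate

`random_parameters()` produces structurally valid parameter sets across
wide ranges (incidence 2–20%, ORs 0.2–1.1, cohorts 100–5000, and so on) for
property-style testing: conservation of cohort mass, monotonicity of
prevented cases in OR and sensitivity, NMB identities, serialization round
trips. It emulates the *shape* of real inputs — families matched to
supports, ordered utilities, CI widths proportional to the estimate — not
their empirical correlations: real screening thresholds trade sensitivity
against specificity along an ROC curve, real costs co-move with setting,
and real utilities correlate within instruments. Tests passing on generated
sets therefore certify the arithmetic and the invariants, not the clinical
realism of any particular input combination; the reference fixture carries
the realism.

## Numerical choices and degenerate inputs

* Probability 1 cannot be rate-converted (infinite rate); `prob_to_rate()`
  refuses it, and the one legitimate appearance — a perfect screen giving
  the positive group a baseline risk of exactly 1 — short-circuits to a
  per-cycle probability of 1.
* 2×2 tables with a zero cell get the Haldane–Anscombe 0.5 correction,
  flagged in the output of `odds_ratio_from_counts()`.
* Beta moment-matching refuses infeasible SEs (se² ≥ mean(1−mean)) with the
  parameter's name, which is how an SE = mean fallback on a parameter with
  mean ≥ 0.5 surfaces rather than silently misbehaving.
* The expected-value cohort engine is validated against an individual-level
  microsimulation oracle (10⁵ agents) to within three binomial standard
  errors of every occupancy.

## Known limitations

The 12-month horizon ignores any persistence of the prevention effect, so
cost-effectiveness may be understated. There is no death state, no relapse
from recovery, no correlation between sampled parameters, and no societal
cost perspective. Several inputs are assumptions flagged as such; the
headline cost totals inherit their uncertainty, which is why the package
treats prevented-case counts and arm rankings — which are robust to those
assumptions — as its primary reproducible outputs.
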