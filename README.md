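# deprev

Cost-effectiveness modelling of depression prevention in primary care.

## The problem

Depression prevention programmes (bibliotherapy, computerised CBT, group
therapy) reduce the risk of onset, and risk algorithms can identify
general-practice attendees at high risk before they become depressed. Is it
worth the NHS's money to screen 1000 GP patients with a risk score, offer
the programme to those above threshold, and treat whoever becomes depressed
anyway — compared with offering the programme to everyone, or doing nothing
beyond treatment as usual (TAU)?

`deprev` is a decision-analytic model for that question, aimed at health
economists and researchers in preventive mental health. It combines:

* a **screening decision tree** splitting the cohort by 12-month incidence
  π and test performance (Se, Sp) into true/false positives/negatives, with
  group risks PPV = *tp*/(*tp*+*fp*) and *fn*/(*tn*+*fn*);
* a **three-state Markov cohort model** (no major depression → depressed →
  recovered, recovered absorbing) in quarterly cycles over 12 months, with
  probabilities rescaled between horizons via *r* = −ln(1−*p*)/*t*,
  *p* = 1−e^(−*rt*);
* a treatment-effect **odds ratio** applied to the screen-positive group's
  baseline risk (multiplicative risk-scale application by default; the
  odds-scale Briggs conversion is available as `or_scale = "odds"`);
* **economics** from the NHS perspective: screening, programme and
  depression-treatment costs, QALYs from state utilities, no discounting,
  and net monetary benefit **NMB = λ·QALYs − cost** at willingness to pay
  λ (£20,000/QALY by default);
* a **probabilistic sensitivity analysis** (beta/gamma/log-normal parameter
  uncertainty, 10,000 draws) with cost-effectiveness acceptability curves,
  plus the standard scenario analyses: risk-score threshold variants,
  alternative ORs, maximum affordable programme cost by effectiveness,
  universal-uptake sweep and half-cycle correction.

## Worked example

```r
library(deprev)
fit <- deprev_model()        # reference parameters, deterministic run
fit
#> Depression-prevention decision model (deterministic run)
#>   cohort 1000 per arm, 4 quarterly cycles, annual incidence 8.8%
#>   screening Se 0.506 / Sp 0.800 at threshold 0.133; OR 0.66 (targeted), 0.90 (universal)
#>   cases prevented vs TAU: 15.1 (risk algorithm + prevention), 8.8 (universal)
#>   optimal arm at WTP GBP 20,000/QALY: predictd_prevention

summary(fit)
#> Costs, QALYs and NMB per cohort at WTP = GBP 20,000 per QALY
#>                   arm cost_screening cost_programme cost_treatment total_cost
#>                   tau              0              0          16576      16576
#>   predictd_prevention          12500          22693          13722      48915
#>  universal_prevention              0         100000          14906     114906
#>  total_qalys incident_cases cases_prevented      nmb per_patient_nmb
#>       846.41           88.0             0.0 16911621           16912
#>       848.75           72.9            15.1 16926083           16926
#>       847.78           79.2             8.8 16840723           16841
#>  strongly_dominated optimal
#>               FALSE   FALSE
#>               FALSE    TRUE
#>                TRUE   FALSE
```

Of the 88 cases expected among 1000 untreated patients, screening at the
base threshold and offering the programme to the 227 screen-positives
prevents about 15; the targeted arm has the highest NMB, and universal
prevention is strongly dominated (more cost, fewer QALYs than the targeted
arm). The PSA propagates parameter uncertainty:

```r
psa <- simulate(fit, nsim = 10000, seed = 1)
psa
#> Probabilistic sensitivity analysis: 10000 simulations (seed 1)
#>   mean cases prevented vs TAU: 15.1 (risk algorithm + prevention), 7.1 (universal)
#>   P(optimal at WTP GBP 20,000/QALY): tau 0.22, predictd_prevention 0.70, universal_prevention 0.08

plot(ceac(psa))              # acceptability curves over WTP £0–£50,000
```

Scenarios and threshold analyses follow the same pattern:

```r
run_scenario("threshold_0.154", n_sims = 1000, seed = 1)   # Se 0.458 / Sp 0.85
max_affordable_cost(or = 0.66, reps = 100, seed = 1)$max_cost
uptake_sweep(reps = 100, seed = 1)
half_cycle_comparison(n_sims = 1000, seed = 1)
```

`reference_parameters()` documents every input, its uncertainty
distribution and whether it is an assumption (`assumed` flag);
`read_parameters()` / `write_parameters()` round-trip parameter sets as
JSON; `random_parameters()` generates valid sets for property testing. See
`vignette("depression-prevention-model")` for the model's assumptions and
numerical conventions.

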