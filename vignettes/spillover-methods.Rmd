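---
title: "Internalizing family health spillovers in cost-effectiveness analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Internalizing family health spillovers in cost-effectiveness analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spillcea)
```

## The problem

Health care interventions change the health of patients' family members as
well as patients themselves: treating a child's behavioral problems relieves
the parents; withdrawing a service elsewhere burdens other families. In
extra-welfarist evaluation — where the objective is to maximize health from a
fixed budget — these *spillovers* sit on both sides of the ledger. Funding a
new intervention generates patient health plus network health, and displaces
patient health plus network health elsewhere in the system. An evaluation
that counts spillovers generated but not spillovers displaced is biased
toward adoption; one that counts neither is only correct by accident.

`spillcea` implements a framework that internalizes both streams with two
multiplier effects, dimensionless ratios of total to patient health:

* `m_i` — the multiplier on health *generated* by the intervention,
  `(Δh_p + Δh_n) / Δh_p`;
* `m_d` — the multiplier on health *displaced* by its funding,
  `(Δh_dp + Δh_dn) / Δh_dp`.

The conventional decision rule "fund iff `Δc / Δh_p < k_p`" (with `k_p` the
cost per unit of displaced patient health) becomes

```
(Δc / Δh_p) * (m_d / m_i) < k_p
```

Strict inequality is used throughout: a tie at the threshold is a rejection.
When `m_i = m_d` the adjustment cancels — constant spillovers across the
system leave conventional, patient-only decisions health-maximizing. The
spillovers only matter for decisions when the two multipliers diverge, and
the package's testing strategy leans on that equivalence: the ratio-form rule
(`spillover_decision()`) is checked against the directly measured-streams
rule (`direct_spillover_decision()`) on thousands of randomly generated
consistent problems.

### Sign conventions and degenerate inputs

Illness-induced losses are stored as negative utility decrements; benefits
of treatment (losses averted) are positive. Multipliers computed from two
same-signed quantities are identical either way, so Table-style negative
decrements can be fed directly to `generated_multiplier()`. The ratio form
divides by `Δh_p` and by `m_i`, so it is refused when `Δh_p = 0` (an
`undefined-multiplier` error pointing at the direct form) and when
`m_i ≤ 0` (net-harmful generated spillovers — representable, but only the
direct form can adjudicate them). Non-positive patient benefit at positive
cost returns a `DOMINATED` verdict rather than an error.

## Reporting precision and the multiplier rounding policy

Internally every multiplier is kept in double precision. Published
multiplier tables are conventionally reported at 2 decimal places, and
integer benefit tables are only reproducible if the reported (rounded)
multipliers — not the raw ratios — are what gets applied. The package
therefore separates the computation layer from the reporting layer:

* `generated_multiplier()` returns the exact ratio;
* `multipliers_from_decrements(p, c, n, digits = 2)` rounds the *per-member
  spillover ratio* `|c|/|p|` to 2 decimals and reports `1 + n × ratio`;
* `perceived_benefit()` applies the 2-dp multiplier and rounds the product
  to the nearest integer, half away from zero.

Rounding the per-member ratio rather than the finished multiplier keeps the
reported values additive in the network size `n`, which is the property the
reference tables satisfy: for behavioral problems the exact two-member ratio
is 0.169/0.109 = 1.5505, which would round to 1.55, while the additive policy
gives 1 + 2 × 0.28 = 1.56 — and only 1.56 is consistent with the published
integer benefits (120 × 1.56 → 187). Half-away-from-zero integer rounding is
likewise reverse-engineered from the published cells (153.6 → 154,
124.8 → 125, 114.4 → 114); both policies are inferences from the printed
values, not stated rules, and `perceived_benefit(..., round_policy = "none")`
exposes the unrounded products for audit.

## The worked funding example

The package ships a fully reproducible stylized funding problem built from
three after-effects of meningitis. A family-impact study of meningitis
survivors estimated mean annual utility decrements (EQ-5D-5L index scale)
for patients and their carers:

```{r}
meningitis_decrements()
```

Six packages of care — a more (A) and a less (B) cost-effective arm per
condition — each cost 2 million currency units. Each 2M of diverted budget
displaces 100 units of patient health (`k_p` = 20,000 per unit) and 16 units
of carer health per affected carer, so the displacement multipliers are 1.16
(one carer) and 1.32 (two). The decision maker recognizes 0, 1 or 2 affected
carers; full information is two:

```{r}
res <- run_portfolio(meningitis_packages())
res$benefits[, c("id", "patient_benefit", "perceived_n1", "perceived_n2")]
res$thresholds
res$realized_net_benefit
```

Patient-only decisions secure 30 units of net health; full-information
decisions secure 109. Keeping full information on the *generated* side but
leaving the threshold unadjusted (`m_d` forced to 1) funds all six packages
and loses a further `displaced_spillover_penalty()` = 32 units relative to
the optimum. The threshold rule is provably optimal here because packages
are independent and equal-cost — the test suite confirms it against
brute-force enumeration of every funding subset — so "full information
dominates" is a theorem the code checks, not an assumption. A
budget-constrained knapsack across unequal-cost packages is deliberately out
of scope.

## Marginal analysis: when are corner solutions optimal?

For a single intervention with divisible quantity, the patient
marginal-health-benefit schedule is modelled as linear and declining,
`MHB_P(q) = intercept − slope·q`, and the marginal health loss `MHL_P` as a
constant (each funding decision is small relative to the budget). Linearity
is the minimal concrete form of the generic declining curve and is a
modelling choice, not an estimate; spillovers are taken proportional to
patient health within an intervention, so `MHB_S = m_i·MHB_P` and
`MHL_S = m_d·MHL_P`. Closed forms follow: the equilibrium
`q* = (intercept − MHL)/slope` (clipped at zero, with a `fund-nothing`
verdict), and welfare triangles as areas between the societal schedules.
Three results fall out, each property-tested against trapezoidal quadrature
and grid search (the quadrature is exact for linear integrands, which is
what makes a 1e-9 agreement tolerance meaningful):

* common scaling of both multipliers leaves `q*` unchanged;
* `m_i > m_d` widens optimal provision, `m_i < m_d` narrows it;
* with small generated spillovers, the optimal policy can be a corner:
  `corner_solution_check()` signs the net benefit integral over `[0, q1]`
  — if scaling back from the patient-only equilibrium gains more (triangle
  B) than the residual surplus (triangle C), nothing should be funded at
  all. When the benefit schedule clears the loss line at `q1` the regime is
  degenerate and the check returns "fund" with B = 0 rather than erroring.

## Estimating decrements and multipliers from cohort data

`estimate_decrements()` runs one ordinary least squares regression per role
(patient, carer): utility on all condition indicators jointly, adjusting for
age, sex and years since illness onset. Joint entry of the conditions was a
genuine design choice — the alternative is one regression per condition —
and was chosen because the reference decrements are marginal impacts holding
the other conditions fixed. Carers carry the linked patient's condition
flags as exposures; without that inheritance the carer-side design matrix
would have no variation to identify condition effects. Collinear designs
raise an error naming the offending columns. No causal machinery (matching,
instruments) and no mixed-effects clustering is attempted; with two carers
per dyad the carer errors are likely correlated within families, so carer
standard errors should be read as slightly optimistic.

`multipliers_from_decrements()` then converts a patient and per-carer
decrement into the generated multiplier at any network size, on magnitudes,
so the estimation output feeds the decision layer directly.
`rank_conditions()` orders conditions by impact magnitude per role; that the
patient and carer orderings can differ (amputations dominate patient losses
while behavioral problems dominate carer losses) is precisely the situation
in which multipliers vary across interventions and spillover information
changes decisions.

## The synthetic cohort generator

No individual-level dataset ships with the package; `generate_cohort()`
emulates the structure the estimation stage assumes so the full pipeline is
testable end to end. Per dyad: condition flags drawn independently by
prevalence, a dyad-level time since onset uniform on 1–25 years, patient age
uniform on 1–40 years (meningitis survivors skew young), carer age uniform
on 20–60, sex Bernoulli(0.5); utilities are baseline + condition decrements
+ linear covariate effects + additive Gaussian noise. The study-scale
defaults are fixed once: 2,000 dyads, 2 carers per patient, noise sd 0.1 on
the utility index, prevalences 0.3/0.3/0.2 for behavioral problems, learning
disability and amputation, baselines 0.90 (patient) and 0.92 (carer), and
covariate effects of −0.002 per year of age, +0.01 for male and +0.001 per
year since onset — small, realistic-scale confounding so the adjustment is
doing real work without dominating the condition effects.

Two deliberate departures from realism are documented rather than patched:
Gaussian noise on a bounded utility index can exceed 1, and the ceiling cap
(`cap_at_one`) is off by default because censoring would bias the OLS
recovery checks that validate the estimator; and condition flags are drawn
independently, with no comorbidity correlation and no spillover decay with
social distance. Passing parameter-recovery tests therefore show that the
estimator recovers the generating process it assumes — not that OLS on a
real, censored, family-clustered EQ-5D-5L sample is unbiased.

Reproducibility: each dyad consumes its own RNG substream (a per-dyad seed
derived from the base seed), so a fixed seed gives bit-identical cohorts and
growing `n_dyads` leaves earlier records untouched.

## Problem sizes and numerical checks

The validation suite uses desk-scale exact checks for everything the worked
example pins down (multipliers, thresholds, the 18 benefit cells, net
benefits 30/109, penalty 32), 10,000 randomized cases for the decision-rule
equivalences, 1,000 random linear instances for the equilibrium geometry
(closed form vs quadrature at 1e-9 absolute), and 200 Monte-Carlo replicates
at the study scale (2,000 dyads, noise sd 0.1) for parameter recovery,
requiring every coefficient within 3 standard errors of truth in at least
95% of replicates; zero-noise cohorts must be recovered to machine
precision.
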