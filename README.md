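# spillcea

Family health spillovers in extra-welfarist cost-effectiveness analysis.

Health care interventions change the health of patients' family networks as
well as patients: treating a child's behavioral problems relieves the
parents, while the budget it absorbs displaces care — and carers' health —
elsewhere. `spillcea` is for health economists and HTA analysts who want to
internalize both sides of that ledger in funding decisions. It provides:

- **Multiplier effects and decision rules** — the ratio of total
  (patient + network) to patient incremental health, specified separately
  for health generated (`m_i`) and displaced (`m_d`), and the adjusted
  decision rule

  ```
  fund  iff  (Δc / Δh_p) · (m_d / m_i) < k_p        (strict)
  ```

  alongside the conventional rule `Δc/Δh_p < k_p` and the direct rule on
  measured streams `Δc/(Δh_p + Δh_n) < Δc_d/(Δh_dp + Δh_dn)`. When
  `m_i = m_d` the adjusted rule collapses exactly onto the conventional one.
- **Portfolio analysis under graded spillover information** — perceived
  benefits, funding thresholds, selected sets, and realized net health
  benefit when the decision maker recognizes 0, 1 or 2 affected carers.
- **Marginal-benefit equilibrium analysis** — linear marginal health
  benefit/loss schedules scaled by the multipliers, equilibrium quantities,
  welfare triangles, and a corner-solution test for when an intervention
  with positive spillovers should not be funded at all.
- **Decrement estimation** — per-role OLS of health utility on condition
  indicators (adjusting for age, sex, years since onset), converted into
  intervention multipliers.
- **A synthetic patient–carer cohort generator** so the whole estimation
  pipeline is testable without external data.

## Worked example

Three after-effects of meningitis carry mean annual utility decrements
(EQ-5D-5L scale) for patients and carers of (−0.109, −0.030) for behavioral
problems, (−0.041, −0.023) for learning disability and (−0.226, −0.005) for
amputations, implying two-carer generated multipliers of 1.56, 2.12 and
1.04. Six packages of care (2M each) are appraised while each 2M of
displaced budget forgoes 100 patient units plus 16 units per affected carer:

```r
library(spillcea)
res <- run_portfolio(meningitis_packages())
res$benefits[, c("id", "patient_benefit", "perceived_n1", "perceived_n2")]
#>            id patient_benefit perceived_n1 perceived_n2
#>  behavioral_A             120          154          187
#>  behavioral_B              80          102          125
#>    learning_A              80          125          170
#>    learning_B              70          109          148
#>  amputation_A             120          122          125
#>  amputation_B             110          112          114
res$thresholds
#>  n0  n1  n2
#> 100 116 132
res$realized_net_benefit
#>  n0  n1  n2
#>  30  86 109
```

Reading this: with patient-only information (threshold 100) the funded set
is behavioral A and both amputation packages, which — once all spillovers
are counted — adds just 30 units of net health. Full two-carer information
(benefits scaled by the 2-dp multipliers, threshold raised to 132) funds
behavioral A and both learning packages instead, adding 109 units. Ignoring
the *displaced* spillovers while counting the generated ones funds all six
packages and loses another 32 units:

```r
displaced_spillover_penalty(meningitis_packages(), scenario_spec(2))
#> [1] 32
```

Single decisions work the same way:

```r
spillover_decision(2e6, 120, multiplier_pair(1.56, 1.32), threshold_spec(20000))
#> <funding_verdict> FUND  ICER: 14102.56  [multiplier]
```

A command-line interface wrapping the same functions is installed at
`inst/cli/spillover-cea`, with subcommands `decide`, `multipliers`,
`portfolio`, `marginal`, `estimate`, `simulate` and `reproduce` (the last
runs the full decrements → multipliers → portfolio chain and self-checks it
against the pinned worked-example values).

See `vignettes/spillover-methods.Rmd` for the model, its assumptions, the
rounding policy that makes the published integer tables reproducible, and
what the synthetic-data tests do and do not establish.

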