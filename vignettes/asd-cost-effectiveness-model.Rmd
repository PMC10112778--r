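---
title: "A lifetime microsimulation of adaptive-behavior interventions in ASD: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lifetime microsimulation of adaptive-behavior interventions in ASD: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asdcem)
```

## The decision problem

`asdcem` models the lifetime clinical and economic consequences of an
intervention that produces a modest improvement in adaptive behavior in young
children with autism spectrum disorder (ASD) and without intellectual
disability. Two strategies are compared: standard of care (SOC — behavioral
and educational interventions), and SOC plus a one-time cord-blood infusion
(CB). The headline outputs are the incremental discounted cost, incremental
discounted QALYs, their ratio (the ICER), and a short-horizon payer budget
impact.

The design is a discrete-time Markov microsimulation: each simulated person
enters at age 2 and is followed in monthly cycles until death or age 100.
Within each month the event order is fixed — death test first, then the
adaptive-behavior score update, then accrual of utility and costs — so
decedents accrue nothing in their death month. Entry (age 2) is time zero for
discounting; both QALYs and costs are discounted at 3%/yr with the
month-start exponent `(1+r)^(-m/12)`. No half-cycle correction is applied: at
monthly resolution its effect is far below Monte-Carlo noise.

## Adaptive behavior (VABS-3)

Adaptive behavior is tracked with the three VABS-3 subscales (communication,
daily living skills, socialization; standard scores, population mean 100, SD
15). The model's state variables per person are the three subscale scores;
the composite is defined as their arithmetic mean (the aggregation rule is
not published; the mean is the neutral choice and all published quantities we
reproduce are differences, which are insensitive to it).

- **Baseline.** One draw from Normal(71.8, 11.8) initializes all three
  subscales (subscale-level baselines are not identifiable from the available
  summaries; utility increments depend only on subscale changes, and the
  level is absorbed by the adult-utility calibration). Draws are clamped to
  the instrument range [20, 140].
- **Natural history.** The composite grows monthly by Normal(0.05, 0.01)
  points during ages 2–4 and Normal(0.14, 0.02) during ages 4–7, applied
  identically to each subscale; growth stops at age 7 (no usable trajectory
  data beyond that age), after which scores are frozen for life. The SDs are
  interpreted as between-individual variation: by default one rate per age
  band is drawn per individual and reused monthly
  (`natural_history.per_individual_rates`); a flag switches to fresh monthly
  draws. The interpretation affects variances only, not means, and no
  published target depends on it.
- **Trial effect.** At entry each person is assigned a 6-month change per
  subscale: communication Normal(3.0, 7.9) under CB vs Normal(0.1, 7.3)
  under SOC; socialization Normal(3.2, 9.2) and daily living Normal(2.8, 6.7)
  in both arms. The change is applied in six equal monthly installments over
  months 0–5, *instead of* the natural-history increment
  (`engine.trial_period_mode = "substitute"`, the default). The substitution
  reading is forced by the published validation pair: the CB-arm 6-month
  communication change validates at ≈2.9 (the trial draw alone) while the
  ages 2–7 composite change validates at ≈6.2 (the growth increments alone,
  reproduced here in a validation mode that disables the trial effect). Under
  a single additive reading those two numbers cannot both hold; the additive
  variant is retained behind the same flag.
- **Adult strata.** At the first monthly step at or beyond age 18 each
  survivor is assigned one of three permanent strata from the frozen
  composite: `>85`, `70–85` (both boundary values belong to the middle
  stratum, matching the printed label), `<70`. Strata drive adult
  productivity-loss costs only.

## Mortality

Annual sex-specific death probabilities come from a period lifetable
(`age,qx_male,qx_female` CSV). Within each year of age the annual qx is held
constant; the monthly rate is `−ln(1−qx)/12`. Standardized mortality ratios
for ASD without intellectual disability (2.49 male, 1.88 female) multiply the
rates at every age from entry to death; male and female rates are then mixed
at the cohort's 78.2% male and converted back to a monthly probability. Sex
is deliberately not a per-person attribute — mixing happens at the rate
level, which is how the published model describes it. The final lifetable row
(age 100) is an absorbing cap with qx = 1. Two fractions male appear in the
source material (78.2% in the input table, 78% in the prose); the model uses
0.782 everywhere.

Because mortality is strategy-independent, the engine draws each person's
death month once by inverse-CDF from the monthly survival curve (one uniform
draw), which is distributionally identical to monthly Bernoulli tests and
makes death times bit-identical across arms under common random numbers.
`life_expectancy_from_age2()` is the analytic counterpart (sum of monthly
survival), used to validate the Monte-Carlo mean age at death.

## Utility and QALYs

For ages 2–17 utility is the published regression of preference-based
utility on VABS-II subscales, ADOS severity and log IQ (natural log by
default; a base-10 option exists and only shifts the level, which
calibration absorbs), with VABS-3 subscales and non-verbal IQ substituted,
then clamped to [−0.36, 1]. ADOS (16.7) and NVIQ (88.1) are fixed at cohort
means — no individual-level distributions are available. From age 18 a
single adult utility constant applies in both arms regardless of VABS-3, so
strategies differ in QALYs only through childhood.

The adult constant's source value is unpublished. The default (0.65) is the
level implied by combining the published SOC undiscounted lifetime QALY level
(40.75) with the published 66.5-year life expectancy; users with the real
2017 US lifetable can recover it exactly with `calibrate_adult_utility()`,
a monotone bisection on [0, 1] against the SOC arm at a fixed seed. Every
incremental quantity (all acceptance targets) is unaffected by the constant,
since adult utility cancels between arms.

Adverse events in the CB arm (month 0, mutually exclusive: severe 3.4%,
mild/moderate 9.2%) charge utility-day decrements (7 and 0.25 days,
i.e. days/365.25 QALYs) directly on the QALY ledger rather than scaling the
utility — the source states the decrements in days. A severe event stops the
therapy: the person's communication change reverts to the SOC distribution
(same underlying normal variate, preserving common random numbers).

## Costs

All costs are 2019 USD/yr, converted to monthly twelfths and discounted like
QALYs. Children (ages 2–17): $19,199 societal, of which $3,395 is the payer
share. Adults: accommodation $20,322, employment support $396, medical
$15,264 (the payer component), non-medical $6,399, caregiver productivity
loss $2,131, individual productivity loss $12,047 — summing to the published
$56,559 at the reference stratum. The individual productivity loss scales
with stratum labor-force participation (60%/40%/20% for >85/70–85/<70) as
`12,047 × (1 − LFP)/(1 − 0.40)`: the published formula is not printed, and
this is the minimal rule that (i) is proportional to non-participation and
(ii) reproduces the published component at the middle stratum. Caregiver
productivity loss is unscaled by default (`adjust_caregiver_productivity`
flag to scale it too). The reduced-adult-cost scenario divides the five
non-individual-productivity components by 3 (`costs.adult_cost_divisor`).
Intervention costs — infusion $15,000 (supported range $3,000–45,000, higher
values standing in for repeat dosing), AE costs $2,100/$11,571 — are month-0
events charged to both perspectives.

## Engine, pairing and reproducibility

Both arms consume one `cohort_randoms` object drawn in a fixed vectorized
order from the run seed: baseline z, four growth-band z's, shared z's for
the three trial changes, the AE uniform and the death uniform. This is the
common-random-numbers design: when CB parameters are set equal to SOC the
two arms are bit-identical, and paired incremental estimates have far
smaller variance than independent seeds (both properties are tested). The
price is that an individual's variates depend on the configured n through
the block layout; `simulate_individual()` therefore reproduces cohort
members for the same (seed, n).

For speed the monthly cycle is evaluated explicitly only while scores can
change (months 0–59); the frozen child period (60–191) and adulthood (192+)
are accrued in closed form per individual from the death month — an exact
reorganization, not an approximation, since utility and cost rates are
constant on those segments. A paired n = 100,000 run takes a few seconds in
pure R.

## Sensitivity analyses and budget impact

- **Tornado** (`tornado()`): one-way parameter sweeps at a fixed seed. The
  published per-parameter ranges are mostly unprinted; the shipped default
  spec is a reconstruction (halve/double ranges for AE costs and rates)
  except the communication-beta extremes 0.0019/0.0074 and the infusion
  range $8,000–45,000, which are published.
- **Two-way grid** (`two_way_grid()`): CB efficacy 1–6 × cost $3,000–33,000,
  ICER per cell classed <50k / 50–100k / 100–150k / >150k. The SOC arm is
  run once (it is unaffected by either parameter).
- **Scenarios** (`scenario()`): pure config transforms
  (`scenario_overrides()` is exported so this is testable). Two readings
  required a decision:
  - *MCID rule*: realized communication draws below the 2.0-point minimal
    clinically important difference are zeroed in **both** arms. Zeroing only
    the treated arm would, counterintuitively, *increase* its mean effect
    (the negative tail of Normal(3.0, 7.9) is zeroed too) and lower the
    ICER, the wrong direction; zeroing sub-threshold changes for everyone
    raises the ICER by ≈1.6×, matching the published result.
  - *"Productivity benefits to 60%/0%"*: implemented as the LFP spread
    across strata — best case widens to {0.80, 0.40, 0.20} (max−min = 60%),
    worst case collapses all strata to the 40% reference (no differential).
  - *Zero efficacy* sets the CB communication distribution equal to SOC's;
    CB then differs only by costs and AE harms, so SOC dominates.
- **Budget impact** (`budget_impact()`): per-person 5-year undiscounted
  payer cost difference from the paired run — recurring child payer costs
  cancel exactly (death times are shared), leaving the infusion plus AE
  costs — scaled by the 247,000 eligible children and uptake. Exactly linear
  in both, by construction.

## The synthetic lifetable, and what a green test establishes

`make_gompertz_lifetable()` generates the test substrate: female hazard
`2e-5 · exp(0.095 · age)`, male 1.6× female, capped at 100. From age 2 this
gives a sex-mixed expectation of death near 80 (SMRs = 1) and ≈70 with the
default SMRs — a modern high-income mortality shape, deliberately *not* a
reproduction of the 2017 US table (life expectancy there validates at 66.5
with these SMRs). Consequences, verified in the test suite:

- Every **incremental** quantity is essentially lifetable-insensitive,
  because the arms differ only before age 18 where survival is ≈1 under any
  plausible table: the undiscounted QALY gain (≈0.163), the CB-arm 6-month
  communication change (≈2.90), the payer ICER at $15,000 (≈$121k/QALY) and
  the budget impact (≈$3.85B) all reproduce the published values on the
  synthetic table.
- **Level** quantities (lifetime QALYs 40.75/16.83, SOC discounted costs
  $1,014,000 societal / $276,000 payer, the societal ICER $105k — which
  nets adult productivity savings against the infusion) shift with adult
  survival: on the synthetic table the societal ICER is ≈$96k and
  high-efficacy/low-cost configurations become outright cost-saving. Those
  published levels are validation targets for users who transcribe the real
  2017 US lifetable into the CSV schema and run
  `calibrate_adult_utility()`; green tests here establish internal
  correctness (closed-form oracles, invariants), not agreement with the
  published absolute levels.

The generator also does not emulate period-vs-cohort effects, cause-deleted
mortality, or time-varying SMRs — all out of scope of the model itself.

## Numerical choices and degenerate inputs

- VABS clamp [20, 140] and utility clamp [−0.36, 1] applied after every
  update; with basecase parameters the ceiling binds for ≲0.1% of
  person-months, producing a relative bias in incremental QALYs well under
  Monte-Carlo noise at n = 100,000 (tested against unclamped closed forms
  within 3 SE).
- Stratum boundaries: 85 and 70 belong to the middle stratum.
- Dominance labels: ICER is reported only when ΔQALY > 0 and ΔCost > 0;
  `dominated` (ΔQ ≤ 0, ΔC > 0), `dominant` (ΔQ ≥ 0, ΔC ≤ 0).
- Calibration bisection: tolerance 0.01 QALYs, 60 iterations max, error if
  the target is outside the [0, 1] utility bracket.
- Zero discount rate, zero SDs, zero mortality (until the cap), n = 1 and
  uptake 0 are all exercised as degenerate cases in the test suite.

## Known limitations

Sex is not an individual attribute (rate-level mixing only); VABS dynamics
end at age 7 for lack of data; adult utility and VABS are decoupled by
assumption, so adult quality-of-life benefits of better adaptive behavior
are not counted (conservative for the intervention); caregiver quality of
life is excluded; treatment effects persist for life with no waning (the
high end of the infusion-cost range proxies for repeat dosing); no
probabilistic sensitivity analysis — parameter uncertainty is explored only
deterministically; and the trial-derived efficacy is a post-hoc subgroup
signal, so results describe a *potential* intervention with that efficacy,
not an established one.
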