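# asdcem

A lifetime patient-level (Markov microsimulation) cost-effectiveness model of
autism spectrum disorder (ASD), for health-economics researchers evaluating
interventions that improve adaptive behavior. It compares two strategies for
children with ASD and without intellectual disability entering at age 2:

- **SOC** — standard of care (behavioral and educational interventions), and
- **CB** — SOC plus a one-time cord-blood infusion.

## The model

Each simulated person is followed **monthly from age 2 to at most 100**,
accruing quality-adjusted life years (QALYs) and costs, discounted at 3%/yr.

- **Adaptive behavior.** Vineland Adaptive Behavior Scale (VABS-3)
  communication, daily-living and socialization subscales start from a
  composite drawn `N(71.8, 11.8)` and grow monthly (`N(0.05, 0.01)`/month at
  ages 2–4, `N(0.14, 0.02)`/month at ages 4–7), freezing at age 7. During
  months 0–5 a trial-derived 6-month subscale change is applied instead:
  communication `N(3.0, 7.9)` under CB vs `N(0.1, 7.3)` under SOC (the
  efficacy signal), socialization `N(3.2, 9.2)` and daily living
  `N(2.8, 6.7)` in both arms.
- **Utility.** For ages 2–17, a published regression
  `u = −0.1630 + 0.0037·comm + 0.0046·dls + 0.0010·soc − 0.005·ADOS +
  0.024·log(IQ)`, clamped to [−0.36, 1]; from age 18 a single adult constant
  identical across arms (so the lifetime QALY gain accrues entirely in
  childhood).
- **Mortality.** Lifetable annual death probabilities converted to monthly
  rates, multiplied by autism-specific standardized mortality ratios
  (2.49 male / 1.88 female), mixed at 78.2% male, converted back to a
  probability. A synthetic Gompertz lifetable generator makes everything run
  with no external data; a transcribed 2017 US lifetable CSV
  (`age,qx_male,qx_female`) can be supplied for the published validation
  numbers.
- **Costs (2019 USD).** Children: $19,199/yr societal, $3,395/yr payer.
  Adults (18+, by VABS-3 stratum >85 / 70–85 / <70): components summing to
  $56,559/yr at the reference stratum, with individual productivity loss
  scaled by labor-force participation (60%/40%/20%). CB adds a $15,000
  infusion at month 0 plus adverse events (9.2% mild/moderate, 3.4% severe,
  with costs and utility decrements; a severe event cancels the treatment
  benefit).
- **Analysis.** Both arms run under common random numbers; incremental
  cost-effectiveness ratio ICER = ΔCost/ΔQALY (discounted), tornado and
  two-way efficacy×cost sensitivity analyses, named scenarios, and a 5-year
  payer budget-impact projection across the 247,000 eligible US children.

## Worked example

```r
library(asdcem)

lt  <- make_gompertz_lifetable()            # synthetic mortality substrate
cfg <- default_config(n = 100000, seed = 1) # all basecase parameters
m   <- run_model(cfg, lifetable = lt)       # paired SOC/CB run

print(m$societal)
print(m$payer)
print(budget_impact(cfg, bia_params(), model = m))
```

prints

```
Incremental result (societal perspective, n = 100000)
  dCost (disc)  $12,410
  dQALY (disc)  0.1291
  ICER          $96,089/QALY [yellow]
Incremental result (payer perspective, n = 100000)
  dCost (disc)  $15,592
  dQALY (disc)  0.1291
  ICER          $120,734/QALY [orange]
Budget impact over 5 years (payer, undiscounted): $3.851B
  per person $15,592, population 247,000, uptake 100%
```

Reading: the infusion buys ≈0.13 discounted QALYs per child (≈0.16
undiscounted, all before age 18). From the payer's view the incremental cost
is just the infusion plus expected adverse-event costs (≈$15,590), giving
≈$121k/QALY; societally, productivity gains from better adult strata offset
part of it. Offering CB to every eligible US child for five years would cost
the payer ≈$3.85B. The absolute QALY/cost levels (not the increments) depend
on the lifetable and the adult utility constant; with the real 2017 US table
(`load_lifetable()`, then `calibrate_adult_utility()`) the model reproduces
the published 66.5-year life expectancy and lifetime cost levels.

Sensitivity machinery:

```r
tornado(cfg, lifetable = lt)                      # one-way DSA, widest first
two_way_grid(cfg, lifetable = lt)                 # efficacy 1-6 x cost 3k-33k
scenario(cfg, "zero_efficacy", lifetable = lt)    # -> dominated
scenario(cfg, "worst_case", lifetable = lt)       # -> multi-million ICER
```

A CLI wrapper ships in `inst/cli/asdcem`
(`Rscript <path>/asdcem run --n 10000 --seed 42 --out results.csv`, plus
`tornado`, `grid`, `bia`, `scenario`, `calibrate`, `make-lifetable`,
`make-config` subcommands).

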