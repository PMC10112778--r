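Package: asdcem
Title: Lifetime Cost-Effectiveness Microsimulation of Adaptive-Behavior
    Interventions in Autism Spectrum Disorder
Version: 0.1.0
Authors@R:
    person("ASD", "Modelling Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A monthly patient-level (Markov microsimulation) model of autism
    spectrum disorder over the lifespan, comparing standard of care with a
    one-time cord-blood infusion strategy. Tracks Vineland Adaptive Behavior
    Scale (VABS-3) subscale trajectories from age 2, maps them to utilities
    through a published regression, applies lifetable mortality with
    autism-specific standardized mortality ratios, and accrues discounted and
    undiscounted QALYs and costs from societal and healthcare-payer
    perspectives. Includes incremental cost-effectiveness analysis with common
    random numbers, deterministic sensitivity analyses (tornado, two-way
    efficacy-by-cost grids, named scenarios), budget-impact projection, and a
    synthetic Gompertz lifetable generator so everything runs with no external
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
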