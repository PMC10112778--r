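test_that("tornado: degenerate ranges give zero span; infusion span is closed form", {
  cfg <- default_config(n = 1500, seed = 43)
  lt <- test_lifetable()
  out <- tornado(cfg, specs = list(
    list(key = "intervention.cost_infusion", low = 15000, high = 15000),
    list(key = "intervention.cost_infusion", low = 8000, high = 45000)
  ), lifetable = lt)
  expect_equal(nrow(out), 2)
  degenerate <- out[out$low == out$high, ]
  expect_equal(degenerate$span, 0)
  wide <- out[out$low != out$high, ]
  dq <- run_model(cfg, lifetable = lt)$societal$delta_qaly
  # time-zero cost linearity: span = 37,000 / dQ
  expect_lt(abs(wide$span - 37000 / dq) / (37000 / dq), 1e-3)
  expect_error(tornado(cfg, specs = list(list(key = "no.such.key", low = 1, high = 2)),
                       lifetable = lt), "unknown config key")
})

test_that("communication beta rescales the QALY gain proportionally", {
  cfg <- default_config(n = 2000, seed = 47)
  # the proportionality holds for the unclamped mapping; lift the utility
  # ceiling so the clamp cannot bind at the high beta
  cfg <- set_config_value(cfg, "qol.utility_max", 5)
  lt <- test_lifetable()
  run_at_beta <- function(b)
    run_model(set_config_value(cfg, "qol.beta_comm", b), lifetable = lt)
  m1 <- run_at_beta(0.0019)
  m2 <- run_at_beta(0.0074)
  # under one seed, dQ + AE decrement is proportional to beta
  led <- m1$cb$ledger
  days <- ifelse(led$adverse_event == "severe", 7,
                 ifelse(led$adverse_event == "mild_moderate", 0.25, 0))
  d_ae <- mean(days / 365.25 * (led$death_month > 0))
  r1 <- (m1$societal$delta_qaly_undisc + d_ae) / 0.0019
  r2 <- (m2$societal$delta_qaly_undisc + d_ae) / 0.0074
  expect_lt(abs(r1 - r2) / r2, 1e-3)
})

test_that("two-way grid is monotone: ICER falls with efficacy, rises with cost", {
  cfg <- default_config(n = 2000, seed = 53)
  g <- two_way_grid(cfg, efficacy_values = c(2, 4, 6),
                    cost_values = c(5000, 15000, 25000),
                    lifetable = test_lifetable())
  expect_equal(nrow(g), 9)
  expect_true(all(g$label %in% c("icer", "dominant")))
  # a cost-saving (dominant) cell ranks below any finite ICER; among dominant
  # cells, larger savings rank lower
  rank_icer <- ifelse(g$label == "dominant", -1e9 + g$delta_cost, g$icer)
  for (cc in unique(g$cost)) {
    col <- rank_icer[g$cost == cc][order(g$efficacy[g$cost == cc])]
    expect_true(all(diff(col) < 0))
  }
  for (ee in unique(g$efficacy)) {
    row <- rank_icer[g$efficacy == ee][order(g$cost[g$efficacy == ee])]
    expect_true(all(diff(row) > 0))
  }
  expect_true(all(g$threshold_class %in%
                    c("green", "yellow", "orange", "red", "dominant")))
})

test_that("named scenarios behave as documented", {
  cfg <- default_config(n = 2000, seed = 59)
  lt <- test_lifetable()
  expect_equal(scenario(cfg, "zero_efficacy", lifetable = lt)$label, "dominated")

  # worst case is a high, finite ICER; best case is at worst a low ICER and
  # in this synthetic world typically cost-saving outright
  best <- scenario(cfg, "best_case", lifetable = lt)
  worst <- scenario(cfg, "worst_case", lifetable = lt)
  expect_equal(worst$label, "icer")
  expect_gt(worst$icer, 1e6)
  expect_true(best$label == "dominant" ||
                (best$label == "icer" && best$icer < worst$icer))

  base <- run_model(cfg, lifetable = lt)
  mcid <- scenario(cfg, "mcid_only", lifetable = lt)
  expect_gt(mcid$icer, base$societal$icer)  # truncation discards small benefits

  pay <- scenario(cfg, "payer", lifetable = lt)
  expect_equal(pay$perspective, "payer")

  reduced <- apply_overrides(cfg, scenario_overrides("reduced_adult_costs"))
  m_red <- run_model(reduced, lifetable = lt)
  expect_lt(m_red$soc$summary$cost_societal_disc,
            base$soc$summary$cost_societal_disc)

  # scenarios are pure config transforms
  direct <- run_model(apply_overrides(cfg, scenario_overrides("zero_efficacy")),
                      lifetable = lt)$societal
  via_wrapper <- scenario(cfg, "zero_efficacy", lifetable = lt)
  expect_equal(direct$delta_qaly, via_wrapper$delta_qaly)
  expect_equal(direct$delta_cost, via_wrapper$delta_cost)
  expect_error(scenario(cfg, "no_such"), "unknown scenario")
})

test_that("budget impact is linear in uptake and population and matches the oracle", {
  cfg <- default_config(n = 20000, seed = 61)
  m <- run_model(cfg, lifetable = test_lifetable())
  full <- budget_impact(cfg, bia_params(uptake = 1), model = m)
  fifth <- budget_impact(cfg, bia_params(uptake = 0.2), model = m)
  none <- budget_impact(cfg, bia_params(uptake = 0), model = m)
  expect_equal(none$total, 0)
  expect_equal(fifth$total, 0.2 * full$total, tolerance = 1e-12)
  half_pop <- budget_impact(cfg, bia_params(eligible_population = 123500), model = m)
  expect_equal(half_pop$total, 0.5 * full$total, tolerance = 1e-12)
  # per-person oracle: infusion + expected AE costs
  expect_lt(abs(full$per_person - 15586.614), 3 * full$per_person_se)
})
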