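test_that("common random numbers: CB identical to SOC when parameters match", {
  cfg <- crn_equal_config(n = 400, seed = 11)
  m <- run_model(cfg, lifetable = test_lifetable())
  led_soc <- m$soc$ledger
  led_cb <- m$cb$ledger
  for (col in c("death_month", "qaly_undisc", "qaly_disc",
                "cost_societal_disc", "cost_payer_disc", "comm_change_6m"))
    expect_identical(led_soc[[col]], led_cb[[col]])
})

test_that("with utility forced to 1 and r = 0, QALYs equal life years from age 2", {
  cfg <- default_config(n = 300, seed = 13)
  cfg$engine$discount_rate <- 0
  cfg$qol$beta0 <- 1
  cfg$qol[c("beta_comm", "beta_dls", "beta_soc", "beta_ados", "beta_logiq")] <- 0
  cfg$qol$adult_utility <- 1
  res <- run_cohort(cfg, "soc", lifetable = test_lifetable())
  expect_equal(res$ledger$qaly_undisc, res$ledger$death_month / 12,
               tolerance = 1e-12)
  expect_equal(res$ledger$qaly_disc, res$ledger$qaly_undisc)
})

test_that("deterministic single path matches an independent monthly rollout", {
  cfg <- default_config(n = 1, seed = 17)
  cfg$engine$discount_rate <- 0
  cfg$natural_history$baseline_composite_sd <- 0
  for (i in seq_along(cfg$natural_history$monthly_change))
    cfg$natural_history$monthly_change[[i]]$sd <- 0
  cfg$intervention$comm_change_soc$sd <- 0
  cfg$intervention$soc_change_both$sd <- 0
  cfg$intervention$dls_change_both$sd <- 0
  res <- run_cohort(cfg, "soc", lifetable = zero_mortality_lifetable())

  # independent scalar rollout of the same stated rules, months 0..191
  comm <- dls <- socs <- 71.8
  qaly <- 0
  for (m in 0:191) {
    if (m < 6) {
      comm <- comm + 0.1 / 6; socs <- socs + 3.2 / 6; dls <- dls + 2.8 / 6
    } else if (m < 60) {
      g <- if (m < 24) 0.05 else 0.14
      comm <- comm + g; socs <- socs + g; dls <- dls + g
    }
    u <- -0.1630 + 0.0037 * comm + 0.0046 * dls + 0.0010 * socs -
      0.005 * 16.7 + 0.024 * log(88.1)
    qaly <- qaly + min(max(u, -0.36), 1) / 12
  }
  child_qaly <- res$ledger$qaly_undisc - cfg$qol$adult_utility * (100 - 18)
  expect_equal(child_qaly, qaly, tolerance = 1e-9)
})

test_that("run_cohort with n = 1 equals simulate_individual", {
  cfg <- default_config(n = 1, seed = 23)
  lt <- test_lifetable()
  res <- run_cohort(cfg, "cb", lifetable = lt)
  one <- simulate_individual(cfg, id = 1, strategy = "cb", lifetable = lt)
  expect_equal(res$ledger, one)
  expect_error(simulate_individual(cfg, id = 2, strategy = "cb", lifetable = lt))
})

test_that("Monte-Carlo mean age at death matches the deterministic oracle", {
  cfg <- default_config(n = 20000, seed = 29)
  lt <- test_lifetable()
  res <- run_cohort(cfg, "soc", lifetable = lt)
  le <- life_expectancy_from_age2(lt, mortality_params())
  expect_lt(abs(res$summary$mean_age_at_death - le),
            3 * res$summary$mean_age_at_death_se)
})

test_that("compare computes ICERs and dominance labels", {
  fake <- function(qd, cd, n = 2) {
    led <- data.frame(qaly_disc = rep(qd, n), qaly_undisc = rep(qd, n),
                      cost_societal_disc = rep(cd, n),
                      cost_societal_undisc = rep(cd, n),
                      cost_payer_disc = rep(cd, n),
                      cost_payer_undisc = rep(cd, n))
    structure(list(summary = list(n = n, seed = 1, discount_rate = 0.03),
                   ledger = led), class = "strategy_result")
  }
  ce <- compare(fake(0, 0), fake(0.133, 14000))
  expect_equal(ce$icer, 14000 / 0.133, tolerance = 1e-9)  # 105,263.16
  expect_equal(ce$threshold_class, "orange")
  expect_equal(compare(fake(0, 0), fake(0, 100))$label, "dominated")
  expect_equal(compare(fake(0, 0), fake(0.1, 0))$label, "dominant")
  expect_error(compare(fake(0, 0), fake(0, 0, n = 3)), "same seed")
})

test_that("ICER is linear in infusion cost with slope 1/dQ", {
  cfg <- default_config(n = 2000, seed = 31)
  lt <- test_lifetable()
  rnd <- cohort_randoms(2000, 31)
  soc <- run_cohort(cfg, "soc", lifetable = lt, randoms = rnd)
  costs <- c(8000, 15000, 25000, 35000, 45000)
  ces <- lapply(costs, function(cc) {
    cfg2 <- set_config_value(cfg, "intervention.cost_infusion", cc)
    compare(soc, run_cohort(cfg2, "cb", lifetable = lt, randoms = rnd))
  })
  icers <- vapply(ces, `[[`, 0, "icer")
  dq <- ces[[1]]$delta_qaly
  expect_true(all(diff(icers) > 0))  # monotone, as in the published table
  slopes <- diff(icers) / diff(costs)
  expect_lt(max(abs(slopes - 1 / dq)) / (1 / dq), 1e-3)
})

test_that("paired (CRN) incremental estimates beat independent seeds on variance", {
  cfg <- default_config(n = 1000, seed = 37)
  lt <- test_lifetable()
  m <- run_model(cfg, lifetable = lt)
  sd_paired <- stats::sd(m$cb$ledger$qaly_disc - m$soc$ledger$qaly_disc)
  cfg2 <- default_config(n = 1000, seed = 38)
  cb_ind <- run_cohort(cfg2, "cb", lifetable = lt)
  sd_indep <- stats::sd(cb_ind$ledger$qaly_disc - m$soc$ledger$qaly_disc)
  expect_lt(sd_paired, sd_indep)
})

test_that("mean age at death is invariant to strategy", {
  cfg <- default_config(n = 1500, seed = 41)
  m <- run_model(cfg, lifetable = test_lifetable())
  expect_identical(m$soc$ledger$death_month, m$cb$ledger$death_month)
})
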