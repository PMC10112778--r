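#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the paired model with each parameter set to its low and high value
#' in turn, holding everything else at base and using the identical seed, and
#' tabulates the societal ICER pair and range width, sorted widest first.
#' Default ranges ship in `inst/extdata/tornado_default.json`; they are a
#' reconstruction (the published per-parameter ranges are mostly unprinted)
#' except for the communication-beta extremes 0.0019/0.0074 and the infusion
#' cost range 8,000-45,000, which are published values.
#'
#' @param config an `asdcem_config`.
#' @param specs list of `list(key =, low =, high =)` dotted-key specs, or a
#'   path to a JSON file of the same shape; `NULL` loads the shipped default.
#' @param lifetable optional `lifetable`.
#' @return data.frame: parameter, low, high, icer_low, icer_high, span
#'   (NA ICERs where an arm is dominated/dominant).
#' @export
tornado <- function(config, specs = NULL, lifetable = NULL) {
  if (is.null(specs))
    specs <- system.file("extdata", "tornado_default.json", package = "asdcem")
  if (is.character(specs))
    specs <- jsonlite::fromJSON(specs, simplifyDataFrame = FALSE)
  lt <- resolve_lifetable(config, lifetable)
  one <- function(key, value) {
    m <- run_model(set_config_value(config, key, value), lifetable = lt)
    m$societal$icer
  }
  rows <- lapply(specs, function(s) {
    il <- one(s$key, s$low); ih <- one(s$key, s$high)
    data.frame(parameter = s$key, low = s$low, high = s$high,
               icer_low = il, icer_high = ih,
               span = abs(ih - il))
  })
  out <- do.call(rbind, rows)
  out[order(-out$span), , drop = FALSE]
}

#' Two-way sensitivity grid: CB efficacy by CB cost
#'
#' Varies the mean 6-month communication change in the CB arm and the
#' infusion cost over a grid, computing the societal ICER per cell from
#' paired runs under one fixed seed (the SOC arm is unaffected by either
#' parameter and is run once). Cells carry the threshold class used in the
#' published heatmap: green <$50k, yellow $50-100k, orange $100-150k,
#' red >$150k per QALY; dominated cells are labelled as such.
#'
#' @param config an `asdcem_config`.
#' @param efficacy_values mean CB communication changes (default 1..6).
#' @param cost_values infusion costs (default $3,000-$33,000 by $5,000).
#' @param lifetable optional `lifetable`.
#' @return data.frame: efficacy, cost, delta_qaly, delta_cost, icer, label,
#'   threshold_class.
#' @export
two_way_grid <- function(config, efficacy_values = seq(1, 6, by = 1),
                         cost_values = seq(3000, 33000, by = 5000),
                         lifetable = NULL) {
  stopifnot(length(efficacy_values) > 0, length(cost_values) > 0)
  lt <- resolve_lifetable(config, lifetable)
  rnd <- cohort_randoms(config$engine$n_individuals, config$engine$seed)
  soc <- run_cohort(config, "soc", lifetable = lt, randoms = rnd)
  grid <- expand.grid(efficacy = efficacy_values, cost = cost_values)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- set_config_value(config, "intervention.comm_change_cb.mean",
                            grid$efficacy[i])
    cfg <- set_config_value(cfg, "intervention.cost_infusion", grid$cost[i])
    cb <- run_cohort(cfg, "cb", lifetable = lt, randoms = rnd)
    ce <- compare(soc, cb, "societal")
    data.frame(efficacy = grid$efficacy[i], cost = grid$cost[i],
               delta_qaly = ce$delta_qaly, delta_cost = ce$delta_cost,
               icer = ce$icer, label = ce$label,
               threshold_class = ifelse(is.na(ce$threshold_class),
                                        ce$label, ce$threshold_class))
  })
  do.call(rbind, rows)
}

#' Override sets defining the named scenarios
#'
#' Every scenario is a pure config transform: applying these dotted-key
#' overrides and running the paired model reproduces the scenario result.
#' `best_case`: $8,000 cost, efficacy 6.0, communication beta 0.0074, widened
#' labor-force-participation spread (0.80/0.40/0.20, max-min = 60%).
#' `worst_case`: $45,000 cost, efficacy 1.0, beta 0.0019, no productivity
#' differential (all strata at the reference LFP). `mcid_only`: realized
#' communication draws below the 2.0-point minimal clinically important
#' difference are set to 0 in both arms, so sub-threshold changes are not
#' credited to anyone.
#' `payer`: healthcare-payer perspective at base parameters.
#' `reduced_adult_costs`: adult non-productivity components divided by 3.
#' `zero_efficacy`: CB communication change distribution set equal to SOC
#' (zero incremental efficacy).
#'
#' @param name scenario name.
#' @return named list of dotted-key overrides.
#' @export
scenario_overrides <- function(name) {
  switch(name,
    best_case = list(
      "intervention.cost_infusion" = 8000,
      "intervention.comm_change_cb.mean" = 6.0,
      "qol.beta_comm" = 0.0074,
      "costs.lfp_by_stratum" = list(gt85 = 0.80, s70to85 = 0.40, lt70 = 0.20)
    ),
    worst_case = list(
      "intervention.cost_infusion" = 45000,
      "intervention.comm_change_cb.mean" = 1.0,
      "qol.beta_comm" = 0.0019,
      "costs.lfp_by_stratum" = list(gt85 = 0.40, s70to85 = 0.40, lt70 = 0.40)
    ),
    mcid_only = list("intervention.mcid_threshold" = 2.0),
    payer = list(),
    reduced_adult_costs = list("costs.adult_cost_divisor" = 3),
    zero_efficacy = list(
      "intervention.comm_change_cb.mean" = 0.1,
      "intervention.comm_change_cb.sd" = 7.3
    ),
    stop("unknown scenario: ", name)
  )
}

#' Run a named scenario
#'
#' @param config an `asdcem_config`.
#' @param name one of `best_case`, `worst_case`, `mcid_only`, `payer`,
#'   `reduced_adult_costs`, `zero_efficacy`.
#' @param lifetable optional `lifetable`.
#' @return the paired `ce_result` (payer perspective for the `payer`
#'   scenario, societal otherwise).
#' @export
scenario <- function(config, name, lifetable = NULL) {
  cfg <- apply_overrides(config, scenario_overrides(name))
  m <- run_model(cfg, lifetable = lifetable)
  if (identical(name, "payer")) m$payer else m$societal
}

#' Budget-impact parameters
#'
#' @param eligible_population eligible US children ages 2-7 with ASD and
#'   without intellectual disability (default 247,000).
#' @param uptake proportion taking up the intervention in \[0,1\].
#' @param horizon_years undiscounted projection horizon (default 5; must stay
#'   within the child cost regime, i.e. at most 16 years from entry at 2).
#' @return a list of class `bia_params`.
#' @export
bia_params <- function(eligible_population = 247000, uptake = 1.0,
                       horizon_years = 5) {
  stopifnot(uptake >= 0, uptake <= 1, horizon_years > 0, horizon_years <= 16)
  structure(list(eligible_population = eligible_population, uptake = uptake,
                 horizon_years = horizon_years), class = "bia_params")
}

#' Budget impact of adopting the CB strategy
#'
#' Per-person incremental undiscounted healthcare-payer cost over the horizon
#' from a paired cohort run (recurring child payer costs cancel under common
#' random numbers since mortality is strategy-independent; the remainder is
#' the infusion plus adverse-event costs), scaled by the eligible population
#' and uptake. Exactly linear in both.
#'
#' @param config an `asdcem_config`.
#' @param bia a `bia_params` list.
#' @param lifetable optional `lifetable`.
#' @param model optional pre-computed `run_model()` output to reuse.
#' @return list of class `bia_result`: `per_person` (USD), `total` (USD),
#'   `total_billions`, plus the inputs.
#' @export
budget_impact <- function(config, bia = bia_params(), lifetable = NULL,
                          model = NULL) {
  if (is.null(model)) model <- run_model(config, lifetable = lifetable)
  mh <- bia$horizon_years * 12
  horizon_payer <- function(res) {
    led <- res$ledger
    ann <- annual_cost(config$costs, 10, NULL, "payer")
    ann / 12 * pmin(led$death_month, mh) + led$month0_payer_cost
  }
  dpp <- horizon_payer(model$cb) - horizon_payer(model$soc)
  per_person <- mean(dpp)
  total <- per_person * bia$eligible_population * bia$uptake
  structure(list(per_person = per_person,
                 per_person_se = stats::sd(dpp) / sqrt(length(dpp)),
                 total = total, total_billions = total / 1e9,
                 eligible_population = bia$eligible_population,
                 uptake = bia$uptake, horizon_years = bia$horizon_years),
            class = "bia_result")
}

#' @export
print.bia_result <- function(x, ...) {
  cat(sprintf(
    "Budget impact over %d years (payer, undiscounted): $%.3fB\n",
    x$horizon_years, x$total_billions))
  cat(sprintf("  per person $%s, population %s, uptake %.0f%%\n",
              format(round(x$per_person), big.mark = ","),
              format(x$eligible_population, big.mark = ","), 100 * x$uptake))
  invisible(x)
}
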