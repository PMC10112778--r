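#' Per-individual random variates for a paired cohort run
#'
#' All randomness for a cohort is drawn up front in one fixed vectorized
#' order from the run seed: baseline composite z, one growth-rate z per age
#' band, shared standard-normal z's for the three 6-month trial changes, the
#' adverse-event uniform, and the death-time uniform. Both strategy arms
#' consume the same object, which implements common random numbers: mortality
#' and all shared draws are identical across arms, and the communication
#' change uses a shared z so arms differ only through parameter values.
#' An individual's variates depend only on (seed, id) for a given n.
#'
#' @param n cohort size.
#' @param seed integer seed.
#' @return list of variate vectors/matrices, class `cohort_randoms`.
#' @export
cohort_randoms <- function(n, seed) {
  set.seed(as.integer(seed))
  structure(list(
    n = as.integer(n), seed = as.integer(seed),
    z_baseline = stats::rnorm(n),
    z_growth = matrix(stats::rnorm(4L * n), nrow = n, ncol = 4L),
    z_comm = stats::rnorm(n),
    z_soc = stats::rnorm(n),
    z_dls = stats::rnorm(n),
    u_ae = stats::runif(n),
    u_death = stats::runif(n)
  ), class = "cohort_randoms")
}

# growth band index (1..4) for month m since entry at age 2
band_of_month <- function(m) findInterval(m, c(0, 24, 36, 48))

# months of accrual in [a, min(M, b)) per individual, undiscounted count and
# discounted sum; cdd = c(0, cumsum(discount factors))
seg_months <- function(M, a, b) pmax(pmin(M, b) - a, 0)
seg_disc <- function(M, a, b, cdd) pmax(cdd[pmin(M, b) + 1L] - cdd[a + 1L], 0)

resolve_lifetable <- function(config, lifetable) {
  if (!is.null(lifetable)) return(lifetable)
  if (!is.null(config$lifetable_path)) return(load_lifetable(config$lifetable_path))
  make_gompertz_lifetable()
}

#' Run one strategy arm of the microsimulation
#'
#' Simulates `n` individuals monthly from age 2: death test first (via the
#' SMR-adjusted sex-mixed monthly probability), then the score update (trial
#' 6-month changes in equal installments over months 0-5, natural-history
#' growth until age 7), then accrual of utility (child regression below 18,
#' adult constant after) and costs; adverse events, infusion and their costs
#' and QALY decrements are month-0 events in the CB arm. Decedents accrue
#' nothing in their death month. The monthly cycle is evaluated explicitly
#' over the score-active months and in exact closed form per individual over
#' the score-frozen months (see the vignette); results are identical to the
#' full monthly loop.
#'
#' @param config an `asdcem_config`.
#' @param strategy `"soc"` or `"cb"`.
#' @param lifetable optional `lifetable`; defaults to `config$lifetable_path`
#'   or the synthetic Gompertz table.
#' @param randoms optional `cohort_randoms` (pass the same object to both
#'   arms for common random numbers); defaults to
#'   `cohort_randoms(n, seed)` from the config.
#' @return a list of class `strategy_result` with `$summary` (cohort means
#'   and standard errors) and `$ledger` (one row per individual).
#' @export
run_cohort <- function(config, strategy = c("soc", "cb"), lifetable = NULL,
                       randoms = NULL) {
  strategy <- match.arg(strategy)
  validate_config(config)
  lt <- resolve_lifetable(config, lifetable)
  eng <- config$engine; nh <- config$natural_history; iv <- config$intervention
  qp <- config$qol; cp <- config$costs; ch <- config$cohort
  n <- eng$n_individuals
  if (is.null(randoms)) randoms <- cohort_randoms(n, eng$seed)
  stopifnot(randoms$n == n)

  mp <- mortality_params(config$mortality$smr_male, config$mortality$smr_female,
                         config$mortality$fraction_male, config$mortality$max_age)
  entry <- ch$entry_age
  n_months <- (mp$max_age - entry) * 12L          # 1176 at defaults
  m_child_end <- (qp$child_age_limit - entry) * 12L  # 192: first adult month
  m_growth_end <- (nh$growth_stop_age - entry) * 12L # 60: scores freeze

  # -- mortality: death month by inverse CDF of the monthly survival curve --
  p_sched <- monthly_death_schedule(lt, mp, entry)   # length n_months + 1
  surv <- cumprod(1 - p_sched)                       # surv[j] = P(M >= j)
  # M = #{j : surv[j] > u}; rev(surv) is nondecreasing
  M <- length(surv) - findInterval(randoms$u_death, rev(surv))

  r <- eng$discount_rate
  disc <- (1 + r)^(-(0:(n_months - 1L)) / 12)
  cdd <- c(0, cumsum(disc))

  # -- baseline and trial-derived draws (shared z's across arms) --
  comm <- dls <- soc <-
    clamp_vabs(nh$baseline_composite_mean +
                 nh$baseline_composite_sd * randoms$z_baseline, nh)
  baseline <- comm

  event <- draw_adverse_event(iv, strategy, u = randoms$u_ae)  # vector
  severe <- event == "severe"
  z6 <- list(comm = randoms$z_comm, soc = randoms$z_soc, dls = randoms$z_dls)
  d_plain <- draw_six_month_changes(iv, strategy, severe_ae = FALSE, z = z6)
  if (strategy == "cb" && any(severe)) {
    d_sub <- draw_six_month_changes(iv, "cb", severe_ae = TRUE, z = z6)
    d_comm <- ifelse(severe, d_sub$comm, d_plain$comm)
  } else d_comm <- d_plain$comm
  d_soc <- d_plain$soc; d_dls <- d_plain$dls
  validation <- isTRUE(eng$validation_mode)
  if (validation) d_comm <- d_soc <- d_dls <- rep(0, n)

  band_mean <- vapply(nh$monthly_change, `[[`, 0, "mean")
  band_sd <- vapply(nh$monthly_change, `[[`, 0, "sd")
  if (isTRUE(nh$per_individual_rates))
    rates <- sweep(sweep(randoms$z_growth, 2, band_sd, `*`), 2, band_mean, `+`)

  qaly_und <- qaly_dis <- numeric(n)
  ew <- iv$effect_window_months
  additive <- identical(eng$trial_period_mode, "additive")

  # -- monthly loop over the score-active period (ages 2 to 7) --
  for (m in 0:(m_growth_end - 1L)) {
    alive <- M > m
    trial_month <- !validation && m < ew
    if (trial_month) {
      comm <- comm + d_comm / ew
      soc <- soc + d_soc / ew
      dls <- dls + d_dls / ew
    }
    if (!trial_month || additive) {
      if (isTRUE(nh$per_individual_rates)) g <- rates[, band_of_month(m)]
      else g <- stats::rnorm(n, band_mean[band_of_month(m)],
                             band_sd[band_of_month(m)])
      comm <- comm + g; soc <- soc + g; dls <- dls + g
    }
    comm <- clamp_vabs(comm, nh); soc <- clamp_vabs(soc, nh)
    dls <- clamp_vabs(dls, nh)
    u <- child_utility(qp, comm, dls, soc, ch$ados_css, ch$nviq)
    qaly_und <- qaly_und + alive * u / 12
    qaly_dis <- qaly_dis + alive * u / 12 * disc[m + 1L]
    if (m == 0L && strategy == "cb") {
      ae <- adverse_event_effects(iv, event)
      month0_cost <- (iv$cost_infusion + ae$cost) * alive
      qaly_und <- qaly_und - ae$qaly_decrement * alive
      qaly_dis <- qaly_dis - ae$qaly_decrement * alive
    }
  }
  if (strategy == "soc") month0_cost <- numeric(n)

  composite7 <- (comm + dls + soc) / 3

  # -- score-frozen childhood, months [60, 192): utility constant --
  u7 <- child_utility(qp, comm, dls, soc, ch$ados_css, ch$nviq)
  qaly_und <- qaly_und + u7 * seg_months(M, m_growth_end, m_child_end) / 12
  qaly_dis <- qaly_dis + u7 * seg_disc(M, m_growth_end, m_child_end, cdd) / 12

  # -- adulthood, months [192, end): constant utility, stratum costs --
  stratum <- vabs_stratum(composite7)
  adult_m <- seg_months(M, m_child_end, n_months)
  adult_d <- seg_disc(M, m_child_end, n_months, cdd)
  qaly_und <- qaly_und + qp$adult_utility * adult_m / 12
  qaly_dis <- qaly_dis + qp$adult_utility * adult_d / 12

  # -- costs (recurring streams are piecewise constant) --
  child_m <- seg_months(M, 0L, m_child_end)
  child_d <- seg_disc(M, 0L, m_child_end, cdd)
  adult_soc_ann <- vapply(c(gt85 = "gt85", s70to85 = "s70to85", lt70 = "lt70"),
                          function(s) annual_cost(cp, 30, s, "societal"), 0)
  adult_pay_ann <- annual_cost(cp, 30, "gt85", "payer")  # stratum-independent
  ann_soc <- adult_soc_ann[stratum]
  cost_soc_und <- cp$child_societal_annual / 12 * child_m +
    ann_soc / 12 * adult_m + month0_cost
  cost_soc_dis <- cp$child_societal_annual / 12 * child_d +
    ann_soc / 12 * adult_d + month0_cost
  cost_pay_und <- cp$child_payer_annual / 12 * child_m +
    adult_pay_ann / 12 * adult_m + month0_cost
  cost_pay_dis <- cp$child_payer_annual / 12 * child_d +
    adult_pay_ann / 12 * adult_d + month0_cost

  ledger <- data.frame(
    id = seq_len(n),
    death_month = M,
    age_at_death = entry + M / 12,
    qaly_undisc = qaly_und, qaly_disc = qaly_dis,
    cost_societal_undisc = cost_soc_und, cost_societal_disc = cost_soc_dis,
    cost_payer_undisc = cost_pay_und, cost_payer_disc = cost_pay_dis,
    month0_payer_cost = month0_cost,
    comm_change_6m = if (validation) NA_real_ else d_comm,
    comp_change_2_7 = ifelse(M >= m_growth_end, composite7 - baseline, NA),
    stratum = stratum,
    adverse_event = event,
    row.names = NULL
  )

  mean_se <- function(x) {
    x <- x[!is.na(x)]
    c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
  }
  adults <- M > m_child_end
  shares <- if (any(adults)) {
    tab <- table(factor(stratum[adults], c("gt85", "s70to85", "lt70")))
    as.numeric(tab) / sum(tab)
  } else rep(NA_real_, 3)
  names(shares) <- c("gt85", "s70to85", "lt70")

  summary <- list(
    strategy = strategy, n = n, seed = randoms$seed, discount_rate = r,
    qaly_undisc = mean(qaly_und), qaly_disc = mean(qaly_dis),
    qaly_undisc_se = stats::sd(qaly_und) / sqrt(n),
    qaly_disc_se = stats::sd(qaly_dis) / sqrt(n),
    cost_societal_undisc = mean(cost_soc_und),
    cost_societal_disc = mean(cost_soc_dis),
    cost_societal_disc_se = stats::sd(cost_soc_dis) / sqrt(n),
    cost_payer_undisc = mean(cost_pay_und),
    cost_payer_disc = mean(cost_pay_dis),
    cost_payer_disc_se = stats::sd(cost_pay_dis) / sqrt(n),
    mean_age_at_death = mean(ledger$age_at_death),
    mean_age_at_death_se = stats::sd(ledger$age_at_death) / sqrt(n),
    mean_comp_change_2_7 = unname(mean_se(ledger$comp_change_2_7)["mean"]),
    mean_comp_change_2_7_se = unname(mean_se(ledger$comp_change_2_7)["se"]),
    mean_comm_change_6m = if (validation) NA_real_ else mean(d_comm),
    mean_comm_change_6m_se = if (validation) NA_real_
      else stats::sd(d_comm) / sqrt(n),
    stratum_shares_at_18 = shares
  )
  structure(list(summary = summary, ledger = ledger),
            class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Strategy %s (n = %d, seed = %d)\n", toupper(s$strategy), s$n, s$seed))
  cat(sprintf("  QALYs   undiscounted %.3f, discounted %.3f\n",
              s$qaly_undisc, s$qaly_disc))
  cat(sprintf("  Costs   societal discounted $%s, payer discounted $%s\n",
              format(round(s$cost_societal_disc), big.mark = ","),
              format(round(s$cost_payer_disc), big.mark = ",")))
  cat(sprintf("  Mean age at death %.1f years\n", s$mean_age_at_death))
  invisible(x)
}

#' Simulate a single individual's ledger
#'
#' Runs the cohort machinery for the configured n and extracts one
#' individual's row; the individual's variates depend only on (seed, id) for
#' that n, so the row is exactly what the full cohort run produces. With
#' `n_individuals = 1` this is the whole cohort.
#'
#' @param config an `asdcem_config`.
#' @param id individual index in 1..n.
#' @param strategy `"soc"` or `"cb"`.
#' @param lifetable optional `lifetable`.
#' @return a one-row data.frame ledger.
#' @export
simulate_individual <- function(config, id = 1L, strategy = "soc",
                                lifetable = NULL) {
  stopifnot(id >= 1, id <= config$engine$n_individuals)
  res <- run_cohort(config, strategy, lifetable = lifetable)
  res$ledger[id, , drop = FALSE]
}

#' Incremental cost-effectiveness of CB versus SOC
#'
#' Pairs the two arms' per-individual ledgers (common random numbers),
#' computes discounted incremental cost and QALYs and the ICER, or a
#' dominance label: `dominated` when the intervention adds cost without QALY
#' gain, `dominant` when it gains QALYs at no added cost. Threshold classes
#' follow the <50k / 50-100k / 100-150k / >150k bands used for the two-way
#' grid, with $100,000/QALY as the headline benchmark.
#'
#' @param soc,cb `strategy_result` objects run under the same seed/config.
#' @param perspective `"societal"` or `"payer"`.
#' @return a list of class `ce_result`: `delta_cost`, `delta_qaly` (and
#'   undiscounted versions and SEs), `icer`, `label`, `threshold_class`.
#' @export
compare <- function(soc, cb, perspective = c("societal", "payer")) {
  perspective <- match.arg(perspective)
  if (soc$summary$n != cb$summary$n || soc$summary$seed != cb$summary$seed ||
      soc$summary$discount_rate != cb$summary$discount_rate)
    stop("arms were not run under the same seed/config")
  cost_col <- paste0("cost_", perspective, "_disc")
  cost_col_u <- paste0("cost_", perspective, "_undisc")
  dq <- cb$ledger$qaly_disc - soc$ledger$qaly_disc
  dc <- cb$ledger[[cost_col]] - soc$ledger[[cost_col]]
  dqu <- cb$ledger$qaly_undisc - soc$ledger$qaly_undisc
  dcu <- cb$ledger[[cost_col_u]] - soc$ledger[[cost_col_u]]
  n <- length(dq)
  delta_qaly <- mean(dq); delta_cost <- mean(dc)
  label <- if (delta_qaly > 0 && delta_cost > 0) "icer"
    else if (delta_qaly <= 0 && delta_cost > 0) "dominated"
    else if (delta_qaly >= 0 && delta_cost <= 0) "dominant"
    else "lower_cost_lower_qaly"
  icer <- if (label == "icer") delta_cost / delta_qaly else NA_real_
  threshold_class <- if (is.na(icer)) NA_character_
    else if (icer < 50000) "green" else if (icer <= 100000) "yellow"
    else if (icer <= 150000) "orange" else "red"
  structure(list(
    perspective = perspective, n = n,
    delta_cost = delta_cost, delta_cost_se = stats::sd(dc) / sqrt(n),
    delta_qaly = delta_qaly, delta_qaly_se = stats::sd(dq) / sqrt(n),
    delta_cost_undisc = mean(dcu), delta_qaly_undisc = mean(dqu),
    delta_qaly_undisc_se = stats::sd(dqu) / sqrt(n),
    icer = icer, label = label, threshold_class = threshold_class
  ), class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("Incremental result (%s perspective, n = %d)\n", x$perspective, x$n))
  cat(sprintf("  dCost (disc)  $%s\n", format(round(x$delta_cost), big.mark = ",")))
  cat(sprintf("  dQALY (disc)  %.4f\n", x$delta_qaly))
  if (x$label == "icer")
    cat(sprintf("  ICER          $%s/QALY [%s]\n",
                format(round(x$icer), big.mark = ","), x$threshold_class))
  else cat(sprintf("  Verdict       %s\n", x$label))
  invisible(x)
}

#' Run both strategy arms under common random numbers
#'
#' @param config an `asdcem_config`.
#' @param lifetable optional `lifetable`.
#' @return list with `soc` and `cb` `strategy_result`s and `societal` /
#'   `payer` `ce_result`s.
#' @export
run_model <- function(config, lifetable = NULL) {
  lt <- resolve_lifetable(config, lifetable)
  rnd <- cohort_randoms(config$engine$n_individuals, config$engine$seed)
  soc <- run_cohort(config, "soc", lifetable = lt, randoms = rnd)
  cb <- run_cohort(config, "cb", lifetable = lt, randoms = rnd)
  list(soc = soc, cb = cb,
       societal = compare(soc, cb, "societal"),
       payer = compare(soc, cb, "payer"))
}
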