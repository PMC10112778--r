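#' Clamp VABS-3 scores to the instrument's standard-score range
#' @keywords internal
clamp_vabs <- function(x, nh) pmin(pmax(x, nh$vabs_floor), nh$vabs_ceiling)

#' Draw a baseline individual state
#'
#' One Normal(mean, sd) draw of the baseline VABS-3 composite (defaults
#' 71.8, 11.8), clamped to the instrument range; all three subscales are
#' initialized to the composite draw (subscale-level baselines are not
#' identifiable from the summary inputs, and utility increments depend only
#' on subscale changes).
#'
#' @param nh natural-history parameter list (`config$natural_history`).
#' @param cohort cohort parameter list (`config$cohort`).
#' @param id integer id for the individual.
#' @return a list of class `individual_state` with fields `id`, `age`,
#'   `alive`, `vabs_comm`, `vabs_dls`, `vabs_soc`, `composite`,
#'   `adult_stratum` ("unassigned"), and zeroed QALY/cost ledgers.
#' @export
draw_baseline <- function(nh, cohort, id = 1L) {
  draw <- clamp_vabs(stats::rnorm(1, nh$baseline_composite_mean,
                                  nh$baseline_composite_sd), nh)
  structure(list(
    id = as.integer(id), age = cohort$entry_age, alive = TRUE,
    vabs_comm = draw, vabs_dls = draw, vabs_soc = draw, composite = draw,
    adult_stratum = "unassigned",
    qaly_undisc = 0, qaly_disc = 0,
    cost_societal_undisc = 0, cost_societal_disc = 0,
    cost_payer_undisc = 0, cost_payer_disc = 0
  ), class = "individual_state")
}

#' Growth-band parameters at a given age
#'
#' @param nh natural-history parameter list.
#' @param age age in years.
#' @return list(mean, sd) of the monthly composite change for the band
#'   covering `age`, or mean 0 / sd 0 at or beyond `growth_stop_age`.
#' @keywords internal
growth_band <- function(nh, age) {
  if (age >= nh$growth_stop_age) return(list(mean = 0, sd = 0))
  for (b in nh$monthly_change)
    if (age >= b$lo && age < b$hi) return(list(mean = b$mean, sd = b$sd))
  stop("no growth band covers age ", age)
}

#' Monthly natural-history increment of the VABS-3 subscales
#'
#' Draws the monthly composite change for the age band containing `age`
#' (defaults: Normal(0.05, 0.01) for ages 2-4, Normal(0.14, 0.02) for ages
#' 4-7, zero from age 7 on when scores freeze). The same increment is added
#' to all three subscales that month. With `per_individual_rates` (the
#' default interpretation) the engine draws one rate per individual per band
#' and reuses it monthly; this function returns a single fresh draw and is
#' the per-month building block.
#'
#' @param nh natural-history parameter list.
#' @param age age in years (must be at or past the entry age, 2).
#' @return a single monthly increment (VABS-3 points).
#' @export
natural_history_increment <- function(nh, age) {
  if (age < 2) stop("natural history is defined from age 2")
  b <- growth_band(nh, age)
  if (b$mean == 0 && b$sd == 0) return(0)
  stats::rnorm(1, b$mean, b$sd)
}

#' Classify a VABS-3 composite into the adult strata
#'
#' Cutoffs follow the instrument's mean 100 / SD 15 convention: `gt85`
#' (composite > 85), `s70to85` (70 <= composite <= 85; both boundaries belong
#' to the middle stratum, matching the "70-85" label), `lt70` (< 70).
#'
#' @param composite VABS-3 composite score(s); vectorized.
#' @return character vector of stratum labels.
#' @export
vabs_stratum <- function(composite) {
  ifelse(composite > 85, "gt85", ifelse(composite >= 70, "s70to85", "lt70"))
}

#' Assign the adult health state at age 18
#'
#' Called at the first monthly step with age >= 18; fixes the stratum from
#' the (frozen) composite. Assigning twice is a contract violation.
#'
#' @param state an `individual_state`.
#' @return the state with `adult_stratum` set.
#' @export
assign_adult_stratum <- function(state) {
  if (state$adult_stratum != "unassigned")
    stop("adult stratum already assigned")
  if (state$age < 18) stop("adult stratum is assigned at age 18, not before")
  state$adult_stratum <- vabs_stratum(state$composite)
  state
}
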