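#' Load a period lifetable from CSV
#'
#' Reads a lifetable with one row per single year of age and sex-specific
#' annual death probabilities. The expected header is
#' `age,qx_male,qx_female` (UTF-8, '.' decimal separator); alternative column
#' names can be mapped through `schema`. Ages must be consecutive integers
#' starting at 0 with no gaps, and every qx must lie in \[0, 1\]. The qx at
#' the final age is treated as 1 by the mortality machinery (absorbing cap)
#' regardless of the stored value.
#'
#' @param path CSV file path.
#' @param schema named character vector mapping the canonical names
#'   `age`, `qx_male`, `qx_female` to the file's column names.
#' @return a `data.frame` of class `lifetable` with columns
#'   `age`, `qx_male`, `qx_female` and attribute `max_age`.
#' @export
load_lifetable <- function(path,
                           schema = c(age = "age", qx_male = "qx_male",
                                      qx_female = "qx_female")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(unname(schema), names(raw))
  if (length(missing))
    stop("lifetable is missing column(s): ", paste(missing, collapse = ", "))
  tab <- data.frame(age = raw[[schema[["age"]]]],
                    qx_male = raw[[schema[["qx_male"]]]],
                    qx_female = raw[[schema[["qx_female"]]]])
  as_lifetable(tab)
}

#' Construct and validate a lifetable
#'
#' @param tab data.frame with numeric columns `age`, `qx_male`, `qx_female`.
#' @return the validated `lifetable`.
#' @export
as_lifetable <- function(tab) {
  stopifnot(all(c("age", "qx_male", "qx_female") %in% names(tab)))
  if (!all(vapply(tab[c("age", "qx_male", "qx_female")], is.numeric, TRUE)))
    stop("lifetable columns must be numeric")
  tab <- tab[order(tab$age), , drop = FALSE]
  if (any(tab$age != round(tab$age))) stop("ages must be integers")
  if (tab$age[1] != 0 || any(diff(tab$age) != 1))
    stop("ages must be consecutive integers 0..max_age with no gaps")
  q <- c(tab$qx_male, tab$qx_female)
  if (any(!is.finite(q)) || any(q < 0) || any(q > 1))
    stop("every qx must lie in [0, 1]")
  rownames(tab) <- NULL
  structure(tab, class = c("lifetable", "data.frame"),
            max_age = max(tab$age))
}

#' Mortality parameters for the simulated cohort
#'
#' Standardized mortality ratios (SMRs) for autism without intellectual
#' disability, applied independently to male and female monthly rates, which
#' are then mixed by the cohort's percent male. Defaults: SMR 2.49 (male),
#' 1.88 (female), 78.2% male, lifetable capped at age 100.
#'
#' @param smr_male,smr_female positive mortality-rate multipliers.
#' @param fraction_male proportion in \[0,1\].
#' @param max_age forced-death cap in years.
#' @return a list of class `mortality_params`.
#' @export
mortality_params <- function(smr_male = 2.49, smr_female = 1.88,
                             fraction_male = 0.782, max_age = 100) {
  stopifnot(smr_male > 0, smr_female > 0,
            fraction_male >= 0, fraction_male <= 1, max_age > 0)
  structure(list(smr_male = smr_male, smr_female = smr_female,
                 fraction_male = fraction_male, max_age = max_age),
            class = "mortality_params")
}

#' Monthly death probability for the simulated ASD cohort
#'
#' Converts the annual sex-specific death probabilities at `floor(age)` to
#' monthly rates, r_s = -ln(1 - qx_s)/12, multiplies each by its SMR, mixes
#' the two rates by the cohort's fraction male, and converts back to a
#' probability:
#' p = 1 - exp(-(f_m r_m SMR_m + (1 - f_m) r_f SMR_f)).
#' Annual qx is held constant within each year of age. Ages at or beyond
#' `max_age` return 1 (forced death at the cap).
#'
#' @param table a `lifetable`.
#' @param params a `mortality_params` list.
#' @param age age(s) in continuous years; vectorized.
#' @return monthly death probabilities in \[0, 1\].
#' @export
monthly_asd_death_probability <- function(table, params, age) {
  if (any(age < 0)) stop("age must be non-negative")
  max_age <- min(params$max_age, attr(table, "max_age"))
  yr <- pmin(floor(age), max_age)
  if (any(floor(age) > attr(table, "max_age") & age < params$max_age))
    stop("lifetable does not cover the requested age")
  idx <- match(yr, table$age)
  if (anyNA(idx)) stop("lifetable does not cover the requested age")
  qm <- table$qx_male[idx]
  qf <- table$qx_female[idx]
  rm_ <- -log1p(-qm) / 12 * params$smr_male
  rf_ <- -log1p(-qf) / 12 * params$smr_female
  p <- -expm1(-(params$fraction_male * rm_ + (1 - params$fraction_male) * rf_))
  p[age >= max_age] <- 1
  p
}

#' Monthly death-probability schedule from an entry age to the cap
#'
#' @param table a `lifetable`.
#' @param params a `mortality_params` list.
#' @param entry_age age in years at model entry (month 0).
#' @return numeric vector of length `(max_age - entry_age) * 12 + 1`:
#'   the death probability faced at the start of months `0, 1, ...`, the last
#'   entry being the forced death at the cap.
#' @keywords internal
monthly_death_schedule <- function(table, params, entry_age = 2) {
  n_months <- (params$max_age - entry_age) * 12
  ages <- entry_age + (0:n_months) / 12
  monthly_asd_death_probability(table, params, ages)
}

#' Deterministic expected age at death from age 2
#'
#' Analytic counterpart of the microsimulation's mortality process: sums
#' monthly survival from age 2 to the cap using the same monthly,
#' SMR-adjusted, sex-mixed probabilities the engine uses (death test at the
#' start of each month). The Monte-Carlo mean age at death converges to this
#' value.
#'
#' @param table a `lifetable`.
#' @param params a `mortality_params` list.
#' @param entry_age entry age in years (default 2).
#' @return expected age at death in years.
#' @export
life_expectancy_from_age2 <- function(table, params, entry_age = 2) {
  p <- monthly_death_schedule(table, params, entry_age)
  surv <- cumprod(1 - p)  # surv[j] = P(alive after the first j death tests)
  entry_age + sum(surv) / 12
}
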