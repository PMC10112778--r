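#' Default model configuration
#'
#' Builds the full nested parameter list for the microsimulation. Defaults are
#' the basecase inputs of the model: a cohort entering at age 2 (78.2% male,
#' NVIQ 88.1, ADOS CSS 16.7), VABS-3 natural history with monthly composite
#' growth by age band, 6-month trial-derived subscale changes for the two
#' strategies, adverse-event rates and costs for the cord-blood arm, the
#' child utility regression with clamping to \[-0.36, 1\], an adult utility
#' constant, child/adult cost blocks with stratum-dependent adult productivity
#' loss, and autism-specific standardized mortality ratios applied to a
#' lifetable.
#'
#' @param n number of simulated individuals per arm.
#' @param seed integer seed for the run (drives all random draws).
#' @param lifetable_path optional path to a lifetable CSV with columns
#'   `age,qx_male,qx_female`; when `NULL` the engine falls back to the
#'   built-in synthetic Gompertz lifetable.
#' @return a nested list of class `asdcem_config` with components `engine`,
#'   `cohort`, `mortality`, `natural_history`, `intervention`, `qol`, `costs`,
#'   `lifetable_path`.
#' @export
default_config <- function(n = 100000L, seed = 1L, lifetable_path = NULL) {
  cfg <- list(
    engine = list(
      n_individuals = as.integer(n),
      seed = as.integer(seed),
      discount_rate = 0.03,
      perspective = "both",
      trial_period_mode = "substitute",  # trial changes replace growth, months 0-5
      validation_mode = FALSE            # TRUE: no trial changes, growth all of ages 2-7
    ),
    cohort = list(
      entry_age = 2,
      fraction_male = 0.782,
      nviq = 88.1,
      ados_css = 16.7
    ),
    mortality = list(
      smr_male = 2.49,
      smr_female = 1.88,
      fraction_male = 0.782,
      max_age = 100
    ),
    natural_history = list(
      baseline_composite_mean = 71.8,
      baseline_composite_sd = 11.8,
      # monthly composite change by age band [lo, hi): mean, sd
      monthly_change = list(
        list(lo = 2, hi = 4, mean = 0.05, sd = 0.01),
        list(lo = 4, hi = 5, mean = 0.14, sd = 0.02),
        list(lo = 5, hi = 6, mean = 0.14, sd = 0.02),
        list(lo = 6, hi = 7, mean = 0.14, sd = 0.02)
      ),
      growth_stop_age = 7,
      vabs_floor = 20,
      vabs_ceiling = 140,
      per_individual_rates = TRUE  # one rate draw per band, reused monthly
    ),
    intervention = list(
      comm_change_soc = list(mean = 0.1, sd = 7.3),
      comm_change_cb = list(mean = 3.0, sd = 7.9),
      soc_change_both = list(mean = 3.2, sd = 9.2),
      dls_change_both = list(mean = 2.8, sd = 6.7),
      p_mild_moderate = 0.092,
      p_severe = 0.034,
      mild_decrement_days = 0.25,
      severe_decrement_days = 7,
      cost_infusion = 15000,
      cost_ae_mild = 2100,
      cost_ae_severe = 11571,
      effect_window_months = 6,
      mcid_threshold = NULL  # when numeric, CB draws below it are set to 0
    ),
    qol = list(
      beta0 = -0.1630,
      beta_comm = 0.0037,
      beta_dls = 0.0046,
      beta_soc = 0.0010,
      beta_ados = -0.005,
      beta_logiq = 0.024,
      log_base = "natural",
      utility_min = -0.36,
      utility_max = 1.0,
      adult_utility = 0.65,  # unprinted in the source; see calibrate_adult_utility()
      child_age_limit = 18
    ),
    costs = list(
      child_societal_annual = 19199,
      child_payer_annual = 3395,
      adult_accommodation = 20322,
      adult_employment_support = 396,
      adult_medical = 15264,
      adult_nonmedical = 6399,
      adult_caregiver_productivity = 2131,
      adult_individual_productivity = 12047,
      lfp_by_stratum = list(gt85 = 0.60, s70to85 = 0.40, lt70 = 0.20),
      lfp_reference = 0.40,
      adjust_caregiver_productivity = FALSE,
      adult_cost_divisor = 1
    ),
    lifetable_path = lifetable_path
  )
  class(cfg) <- "asdcem_config"
  validate_config(cfg)
}

#' Validate a model configuration
#'
#' Checks type/range invariants (probabilities in \[0,1\], non-negative costs
#' and sds, AE probabilities summing to at most 1, utility bounds ordered).
#'
#' @param config an `asdcem_config` list.
#' @return the config, invisibly unchanged, or an error.
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  iv <- config$intervention
  if (iv$p_mild_moderate < 0 || iv$p_severe < 0 ||
      iv$p_mild_moderate + iv$p_severe > 1)
    stop("adverse-event probabilities must be in [0,1] and sum to <= 1")
  if (any(c(iv$cost_infusion, iv$cost_ae_mild, iv$cost_ae_severe) < 0))
    stop("intervention costs must be non-negative")
  sds <- c(iv$comm_change_soc$sd, iv$comm_change_cb$sd,
           iv$soc_change_both$sd, iv$dls_change_both$sd,
           config$natural_history$baseline_composite_sd,
           vapply(config$natural_history$monthly_change, `[[`, 0, "sd"))
  if (any(sds < 0)) stop("standard deviations must be non-negative")
  mt <- config$mortality
  if (mt$smr_male <= 0 || mt$smr_female <= 0) stop("SMRs must be positive")
  if (mt$fraction_male < 0 || mt$fraction_male > 1)
    stop("fraction_male must be in [0,1]")
  q <- config$qol
  if (q$utility_min >= q$utility_max) stop("utility_min must be < utility_max")
  if (q$adult_utility < q$utility_min || q$adult_utility > q$utility_max)
    stop("adult_utility outside utility bounds")
  cs <- config$costs
  if (any(unlist(cs$lfp_by_stratum) < 0 | unlist(cs$lfp_by_stratum) > 1))
    stop("labor-force participation must be in [0,1]")
  if (cs$adult_cost_divisor <= 0) stop("adult_cost_divisor must be positive")
  nh <- config$natural_history
  if (nh$vabs_floor >= nh$vabs_ceiling) stop("vabs_floor must be < vabs_ceiling")
  if (config$engine$discount_rate < 0) stop("discount_rate must be >= 0")
  if (config$engine$n_individuals < 1) stop("n_individuals must be >= 1")
  invisible(config)
}

#' Set a configuration value by dotted key
#'
#' Scenario and sensitivity machinery address parameters as dotted paths,
#' e.g. `"intervention.cost_infusion"` or `"qol.beta_comm"`. The key must
#' already exist in the config; unknown keys are an error (this is what makes
#' scenario override sets pure config transforms).
#'
#' @param config an `asdcem_config` list.
#' @param key dotted path into the nested list.
#' @param value replacement value.
#' @return the modified config.
#' @export
set_config_value <- function(config, key, value) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  node <- config
  for (p in parts[-length(parts)]) {
    if (!is.list(node) || !(p %in% names(node)))
      stop("unknown config key: ", key)
    node <- node[[p]]
  }
  if (!is.list(node) || !(parts[length(parts)] %in% names(node)))
    stop("unknown config key: ", key)
  config[[parts]] <- value
  validate_config(config)
  config
}

#' Apply a named list of dotted-key overrides
#' @param config an `asdcem_config` list.
#' @param overrides named list, names are dotted keys.
#' @return the modified config.
#' @export
apply_overrides <- function(config, overrides) {
  for (k in names(overrides)) config <- set_config_value(config, k, overrides[[k]])
  config
}

#' Read / write a model configuration as JSON
#'
#' @param path file path.
#' @return `load_config` returns an `asdcem_config`; `save_config` returns
#'   the path invisibly.
#' @export
load_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  # restore scalar/list shapes jsonlite may have altered
  cfg$natural_history$monthly_change <-
    lapply(cfg$natural_history$monthly_change, as.list)
  class(cfg) <- "asdcem_config"
  validate_config(cfg)
}

#' @rdname load_config
#' @param config an `asdcem_config` list.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
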