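#' Synthetic Gompertz lifetable
#'
#' Generates a plausible period lifetable from a Gompertz hazard so that the
#' whole package builds and tests with no external data. Female annual hazard
#' h_f(a) = alpha * exp(beta_g * a); male hazard is `sex_hazard_ratio` times
#' the female hazard; qx_sex(a) = 1 - exp(-h_sex(a)). The row at `max_age` is
#' forced to qx = 1 (absorbing cap). Defaults (alpha 2e-5, slope 0.095/yr,
#' male:female hazard ratio 1.6) give a sex-mixed expectation of age at death
#' from age 2 of roughly 80 years, i.e. a modern high-income lifetable shape.
#' This stands in for, and does not reproduce, the 2017 US lifetable; see the
#' vignette for how to supply the real one.
#'
#' @param alpha baseline annual hazard (> 0).
#' @param beta_g log-hazard slope per year of age (> 0).
#' @param max_age final age row (forced death).
#' @param sex_hazard_ratio male:female hazard ratio.
#' @return a `lifetable`.
#' @export
make_gompertz_lifetable <- function(alpha = 2e-5, beta_g = 0.095,
                                    max_age = 100, sex_hazard_ratio = 1.6) {
  stopifnot(alpha > 0, beta_g > 0, max_age > 1, sex_hazard_ratio > 0)
  age <- 0:max_age
  h_f <- alpha * exp(beta_g * age)
  h_m <- sex_hazard_ratio * h_f
  qx_female <- -expm1(-h_f)
  qx_male <- -expm1(-h_m)
  if (any(pmax(qx_male, qx_female)[age < 60] >= 1))
    stop("implausible Gompertz parameters: qx reaches 1 before age 60")
  qx_female[age == max_age] <- 1
  qx_male[age == max_age] <- 1
  as_lifetable(data.frame(age = age, qx_male = qx_male, qx_female = qx_female))
}

#' Write a lifetable to the standard CSV schema
#'
#' Header `age,qx_male,qx_female`, one row per single year of age. The same
#' schema accepts a transcription of a real period lifetable (e.g. the 2017
#' US table, single-year male/female qx columns) for the external-data
#' validation targets.
#'
#' @param table a `lifetable`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_lifetable <- function(table, path) {
  utils::write.csv(as.data.frame(table)[c("age", "qx_male", "qx_female")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a complete fixture configuration
#'
#' Serializes `default_config()` (all basecase parameters), optionally with
#' dotted-key overrides, to JSON. With no overrides the output reproduces the
#' documented defaults byte-for-byte on every call.
#'
#' @param path output JSON path.
#' @param overrides named list of dotted-key overrides
#'   (e.g. `list("intervention.cost_infusion" = 45000)`); unknown keys error.
#' @param n,seed engine size and seed stored in the fixture (small n keeps
#'   test fixtures fast).
#' @param lifetable_path lifetable CSV path stored in the config, or NULL for
#'   the built-in synthetic table.
#' @return the config that was written, invisibly.
#' @export
make_fixture_config <- function(path, overrides = list(), n = 2000L,
                                seed = 20230418L, lifetable_path = NULL) {
  cfg <- default_config(n = n, seed = seed, lifetable_path = lifetable_path)
  cfg <- apply_overrides(cfg, overrides)
  save_config(cfg, path)
  invisible(cfg)
}
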