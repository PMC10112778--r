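# shared fixtures and independent oracles

# memoized synthetic lifetable (identical across test files)
test_lifetable <- local({
  lt <- NULL
  function() {
    if (is.null(lt)) lt <<- make_gompertz_lifetable()
    lt
  }
})

# direct month-by-month lifetable summation, written independently of the
# package's vectorized path: plain loop, scalar arithmetic
le_direct_oracle <- function(tab, smr_m = 1, smr_f = 1, fm = 0.782,
                             entry = 2, max_age = 100) {
  total <- 0
  s <- 1
  for (m in 0:((max_age - entry) * 12)) {
    age_now <- entry + m / 12
    yr <- floor(age_now)
    if (age_now >= max_age) {
      p <- 1
    } else {
      qm <- tab$qx_male[tab$age == yr]
      qf <- tab$qx_female[tab$age == yr]
      p <- 1 - exp(-(fm * smr_m * (-log(1 - qm) / 12) +
                       (1 - fm) * smr_f * (-log(1 - qf) / 12)))
    }
    s <- s * (1 - p)
    total <- total + s
  }
  entry + total / 12
}

# monthly survival curve S[j] = P(alive after j death tests), computed the
# same way as le_direct_oracle (used by the acceptance closed-form oracles)
survival_curve_oracle <- function(tab, smr_m = 2.49, smr_f = 1.88,
                                  fm = 0.782, entry = 2, max_age = 100) {
  n_months <- (max_age - entry) * 12
  s <- numeric(n_months + 1)
  cur <- 1
  for (m in 0:n_months) {
    age_now <- entry + m / 12
    yr <- floor(age_now)
    if (age_now >= max_age) {
      p <- 1
    } else {
      qm <- tab$qx_male[tab$age == yr]
      qf <- tab$qx_female[tab$age == yr]
      p <- 1 - exp(-(fm * smr_m * (-log(1 - qm) / 12) +
                       (1 - fm) * smr_f * (-log(1 - qf) / 12)))
    }
    cur <- cur * (1 - p)
    s[m + 1] <- cur
  }
  s
}

# config where the CB arm is parameter-identical to SOC (common-random-number
# identity fixture)
crn_equal_config <- function(n = 500, seed = 11) {
  cfg <- default_config(n = n, seed = seed)
  cfg <- set_config_value(cfg, "intervention.comm_change_cb.mean", 0.1)
  cfg <- set_config_value(cfg, "intervention.comm_change_cb.sd", 7.3)
  cfg <- set_config_value(cfg, "intervention.p_mild_moderate", 0)
  cfg <- set_config_value(cfg, "intervention.p_severe", 0)
  cfg <- set_config_value(cfg, "intervention.cost_infusion", 0)
  cfg
}

# write a lifetable data.frame to a temp CSV
write_temp_lifetable <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# lifetable with no mortality until the forced cap
zero_mortality_lifetable <- function(max_age = 100) {
  as_lifetable(data.frame(age = 0:max_age,
                          qx_male = c(rep(0, max_age), 1),
                          qx_female = c(rep(0, max_age), 1)))
}
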