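#' Annual cost of ASD by age, adult stratum and perspective
#'
#' Children (ages 2-17): $19,199/yr societal (healthcare, school, therapies,
#' caregiver time), of which $3,395/yr is the healthcare-payer share. Adults
#' (18+): the payer pays the medical-services component ($15,264/yr); the
#' societal perspective adds accommodation, employment support, non-medical
#' services and caregiver productivity loss, plus an individual productivity
#' loss scaled by the stratum's labor-force participation:
#' loss = 12,047 * (1 - LFP(stratum)) / (1 - 0.40), so the middle stratum
#' (LFP 40%) reproduces the published component, and the components then sum
#' to the published adult total of $56,559/yr. `adult_cost_divisor` (default
#' 1; 3 in the reduced-adult-cost scenario) divides the non-individual-
#' productivity adult components only.
#'
#' @param cp cost parameter list (`config$costs`).
#' @param age age in years.
#' @param stratum adult stratum (`"gt85"`, `"s70to85"`, `"lt70"`); required
#'   iff `age >= 18`.
#' @param perspective `"societal"` or `"payer"`.
#' @return annual cost in 2019 USD.
#' @export
annual_cost <- function(cp, age, stratum = NULL, perspective = "societal") {
  perspective <- match.arg(perspective, c("societal", "payer"))
  if (age < 18) {
    return(if (perspective == "payer") cp$child_payer_annual
           else cp$child_societal_annual)
  }
  if (is.null(stratum) || !stratum %in% c("gt85", "s70to85", "lt70"))
    stop("an adult stratum is required at ages 18+")
  if (perspective == "payer") return(cp$adult_medical / cp$adult_cost_divisor)
  lfp <- cp$lfp_by_stratum[[stratum]]
  scale <- (1 - lfp) / (1 - cp$lfp_reference)
  fixed <- cp$adult_accommodation + cp$adult_employment_support +
    cp$adult_medical + cp$adult_nonmedical
  caregiver <- cp$adult_caregiver_productivity *
    (if (isTRUE(cp$adjust_caregiver_productivity)) scale else 1)
  (fixed + caregiver) / cp$adult_cost_divisor +
    cp$adult_individual_productivity * scale
}

#' Monthly cost increment for an individual state
#'
#' annual_cost/12, discounted with the month-start exponent. Intervention and
#' adverse-event costs are month-0 events charged by the engine (discount
#' factor 1 at time zero) and are not part of this recurring stream.
#'
#' @param cp cost parameter list.
#' @param state an `individual_state` (uses `age` and `adult_stratum`).
#' @param perspective `"societal"` or `"payer"`.
#' @param discount_rate annual discount rate.
#' @param months_since_entry non-negative integer month index.
#' @return list(undiscounted, discounted) in USD.
#' @export
monthly_cost <- function(cp, state, perspective = "societal",
                         discount_rate = 0.03, months_since_entry = 0) {
  stratum <- if (state$age >= 18) state$adult_stratum else NULL
  ann <- annual_cost(cp, state$age, stratum, perspective)
  und <- ann / 12
  list(undiscounted = und,
       discounted = und * (1 + discount_rate)^(-months_since_entry / 12))
}
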