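#' Base-case model parameters
#'
#' Returns the complete base-case parameter set for the watchful-waiting
#' versus immediate-ED-transfer comparison: epidemiological probabilities,
#' unit costs in 2022 Canadian dollars, health-state utilities, and economic
#' settings. Derived fields (the ED-visit probability under watchful waiting,
#' the immediate-arm epinephrine cost, indirect visit costs, and the per-day
#' out-of-hospital fatality probability in the watchful-waiting state) are
#' populated by the derivation functions so that they always satisfy their
#' defining identities.
#'
#' @return An object of class `ww_parameters`: a list with components
#'   `epi`, `cost`, `util` and `settings`.
#' @seealso [derive_ed_visit_prob()], [derive_ww_out_of_hospital_fatality()],
#'   [apply_fatality_multiplier()]
#' @export
#' @examples
#' p <- default_parameters()
#' p$epi$p_ed_ww          # 0.14
#' p$cost$epi_cost_immediate_ed  # 52.1
default_parameters <- function() {
  epi <- list(
    p_severe_annual = 0.087,
    p_no_eai = 0.094,
    p_biphasic = 0.046,
    p_ed_ww = NA_real_,               # derived
    p_hosp_given_ed = 1.68e-3,
    p_fatal_hosp = 4.5e-3,
    p_fatal_overall_annual = 6.9e-7,
    ww_fatality_multiplier = 10,
    p_remission_annual = 0.058,
    remission_min_age = 1,
    remission_max_age = 6,
    p_fa_ww_daily = NA_real_,         # derived
    p_fa_ww_annual = NA_real_         # derived (annualized reporting form)
  )
  cost <- list(
    eai_unit_cost = 95,
    ed_injection_cost = 0.80,
    p_eai_before_ed = 0.54,
    epi_cost_immediate_ed = NA_real_, # derived
    ambulance_cost = 848,
    ed_visit_medical_cost = 331,
    hosp_daily_cost = 1866,
    annual_fa_medical_cost = 1388,
    annual_remission_medical_cost = 569,
    ed_oop_cost = 95,
    annual_fa_oop_cost = 2577,
    annual_fa_indirect_cost = 4421,
    hourly_wage = 31.37,
    ed_wait_hours = 3.6,
    hosp_workday_hours = 8,
    ed_indirect_cost = NA_real_,      # derived
    hosp_indirect_cost = NA_real_     # derived
  )
  util <- list(
    u_food_allergy = 0.92,
    disutility_reaction = 0.09,
    u_remission = 0.93
  )
  settings <- list(
    discount_rate_annual = 0.015,
    wtp = 50000,
    horizon_years = 20,
    cycle_days = 1,
    days_per_year = 365,
    start_age_years = 1,
    perspective = "healthcare"
  )
  params <- structure(list(epi = epi, cost = cost, util = util,
                           settings = settings),
                      class = "ww_parameters")
  params <- rederive_parameters(params)
  validate_parameters(params)
  params
}

#' Recompute all derived parameter fields
#'
#' Re-applies the defining arithmetic for every derived field after any raw
#' field has changed (sensitivity analysis, probabilistic draws, config
#' overrides). Fields named in `keep` are left at their current value, which
#' is how the deterministic sensitivity analysis varies a derived quantity
#' such as the immediate-arm epinephrine cost directly.
#'
#' @param params A `ww_parameters` object.
#' @param keep Character vector of derived field names to leave untouched.
#' @return The updated `ww_parameters` object.
#' @export
rederive_parameters <- function(params, keep = character()) {
  if (!"p_ed_ww" %in% keep) {
    params$epi$p_ed_ww <- derive_ed_visit_prob(params$epi$p_no_eai,
                                               params$epi$p_biphasic)
  }
  if (!"epi_cost_immediate_ed" %in% keep) {
    params$cost$epi_cost_immediate_ed <- derive_epi_cost_immediate(
      params$cost$ed_injection_cost, params$cost$eai_unit_cost,
      params$cost$p_eai_before_ed)
  }
  if (!"ed_indirect_cost" %in% keep) {
    params$cost$ed_indirect_cost <-
      params$cost$ed_wait_hours * params$cost$hourly_wage
  }
  if (!"hosp_indirect_cost" %in% keep) {
    params$cost$hosp_indirect_cost <-
      params$cost$hosp_workday_hours * params$cost$hourly_wage
  }
  if (!"p_fa_ww_daily" %in% keep) {
    fa <- derive_ww_out_of_hospital_fatality(params)
    params$epi$p_fa_ww_daily <- fa$per_day
    params$epi$p_fa_ww_annual <- fa$annual
  }
  params
}

#' Validate a parameter set against its type invariants
#'
#' Checks that every probability lies in \[0, 1\], costs are nonnegative,
#' utilities net of the reaction disutility stay in \[0, 1\], the fatality
#' multiplier is at least 1, and the derived fields match their defining
#' identities. Errors with the name of the offending field.
#'
#' @param params A `ww_parameters` object.
#' @return `params`, invisibly, if valid.
#' @export
validate_parameters <- function(params) {
  e <- params$epi; co <- params$cost; u <- params$util; s <- params$settings
  probs <- c(p_severe_annual = e$p_severe_annual, p_no_eai = e$p_no_eai,
             p_biphasic = e$p_biphasic, p_ed_ww = e$p_ed_ww,
             p_hosp_given_ed = e$p_hosp_given_ed, p_fatal_hosp = e$p_fatal_hosp,
             p_fatal_overall_annual = e$p_fatal_overall_annual,
             p_remission_annual = e$p_remission_annual,
             p_fa_ww_daily = e$p_fa_ww_daily,
             p_eai_before_ed = co$p_eai_before_ed)
  bad <- names(probs)[!is.finite(probs) | probs < 0 | probs > 1]
  if (length(bad)) stop("probability out of [0,1]: ", paste(bad, collapse = ", "))
  costs <- unlist(co[c("eai_unit_cost", "ed_injection_cost",
                       "epi_cost_immediate_ed", "ambulance_cost",
                       "ed_visit_medical_cost", "hosp_daily_cost",
                       "annual_fa_medical_cost", "annual_remission_medical_cost",
                       "ed_oop_cost", "annual_fa_oop_cost",
                       "annual_fa_indirect_cost", "hourly_wage",
                       "ed_wait_hours", "hosp_workday_hours",
                       "ed_indirect_cost", "hosp_indirect_cost")])
  bad <- names(costs)[!is.finite(costs) | costs < 0]
  if (length(bad)) stop("negative or non-finite cost: ", paste(bad, collapse = ", "))
  if (e$ww_fatality_multiplier < 1) stop("ww_fatality_multiplier must be >= 1")
  if (e$remission_min_age >= e$remission_max_age)
    stop("remission_min_age must be below remission_max_age")
  for (nm in c("u_food_allergy", "u_remission")) {
    if (u[[nm]] < 0 || u[[nm]] > 1) stop(nm, " outside [0,1]")
  }
  if (u$disutility_reaction < 0) stop("disutility_reaction must be >= 0")
  if (s$discount_rate_annual < 0) stop("discount_rate_annual must be >= 0")
  if (s$horizon_years <= 0) stop("horizon_years must be > 0")
  if (!s$perspective %in% c("healthcare", "societal"))
    stop("perspective must be 'healthcare' or 'societal'")
  invisible(params)
}

#' ED-visit probability under watchful waiting
#'
#' The probability that a severe reaction managed by watchful waiting ends
#' up in the emergency department: the fraction of patients without an
#' autoinjector plus the fraction whose reaction is biphasic, capped at 1.
#'
#' @param p_no_eai Probability of not carrying an autoinjector.
#' @param p_biphasic Probability of a biphasic reaction after autoinjector use.
#' @return A probability.
#' @export
#' @examples
#' derive_ed_visit_prob(0.094, 0.046)  # 0.14
derive_ed_visit_prob <- function(p_no_eai, p_biphasic) {
  stopifnot(is.finite(p_no_eai), is.finite(p_biphasic))
  if (p_no_eai < 0 || p_no_eai > 1 || p_biphasic < 0 || p_biphasic > 1)
    stop("inputs must be probabilities in [0,1]")
  min(1, p_no_eai + p_biphasic)
}

#' Per-patient epinephrine cost in the immediate-transfer arm
#'
#' In-ED injection cost plus the expected cost of the autoinjector used at
#' home before transfer (unit cost times the probability of pre-ED use).
#'
#' @param ed_injection_cost Cost of an in-ED epinephrine injection (CAD).
#' @param eai_unit_cost Autoinjector replacement cost (CAD).
#' @param p_eai_before_ed Probability an autoinjector was used before the ED.
#' @return Cost in CAD.
#' @export
#' @examples
#' derive_epi_cost_immediate(0.80, 95, 0.54)  # 52.1
derive_epi_cost_immediate <- function(ed_injection_cost, eai_unit_cost,
                                      p_eai_before_ed) {
  if (ed_injection_cost < 0 || eai_unit_cost < 0) stop("costs must be >= 0")
  if (p_eai_before_ed < 0 || p_eai_before_ed > 1)
    stop("p_eai_before_ed must be in [0,1]")
  ed_injection_cost + p_eai_before_ed * eai_unit_cost
}

#' Indirect cost of a visit from lost productivity
#'
#' Hours of caregiver time multiplied by the average hourly wage, rounded to
#' the nearest dollar for reporting.
#'
#' @param hours Length of stay in hours.
#' @param wage Hourly wage (CAD).
#' @return Cost in CAD, rounded to the dollar.
#' @export
derive_indirect_visit_cost <- function(hours, wage) {
  stopifnot(hours >= 0, wage >= 0)
  round(hours * wage)
}

#' Convert an annual probability to a per-cycle (daily) probability
#'
#' Uses the constant-rate compounding identity
#' `1 - (1 - p_annual)^(1/days_per_year)`.
#'
#' @param p_annual Annual probability in \[0, 1).
#' @param days_per_year Cycles per year (default 365).
#' @return Per-cycle probability.
#' @export
annual_to_cycle_prob <- function(p_annual, days_per_year = 365) {
  if (any(p_annual < 0 | p_annual >= 1))
    stop("p_annual must be in [0,1): the implied daily rate is undefined at 1")
  # log1p/expm1 keep the round trip with cycle_to_annual_prob exact to
  # near machine precision even for small probabilities
  -expm1(log1p(-p_annual) / days_per_year)
}

#' Convert a per-cycle probability back to an annual probability
#'
#' Inverse of [annual_to_cycle_prob()].
#'
#' @param p_cycle Per-cycle probability in \[0, 1\].
#' @param days_per_year Cycles per year (default 365).
#' @return Annual probability.
#' @export
cycle_to_annual_prob <- function(p_cycle, days_per_year = 365) {
  if (any(p_cycle < 0 | p_cycle > 1)) stop("p_cycle must be in [0,1]")
  -expm1(days_per_year * log1p(-p_cycle))
}

#' Calibrated ED-to-hospital admission probability
#'
#' Solves for the admission probability `p_h` such that, under universal
#' immediate ED transfer, annual severe-reaction incidence times `p_h` times
#' the in-hospital fatality probability equals the overall annual
#' food-allergy fatality probability.
#'
#' @param p_severe_annual Annual probability of a severe reaction.
#' @param p_fatal_overall_annual Overall annual food-allergy fatality
#'   probability.
#' @param p_fatal_hosp In-hospital food-allergy fatality probability per
#'   admission.
#' @return The admission probability.
#' @export
#' @examples
#' calibrate_hospitalization_prob(0.087, 6.9e-7, 4.5e-3)  # 1.7625e-3
calibrate_hospitalization_prob <- function(p_severe_annual,
                                           p_fatal_overall_annual,
                                           p_fatal_hosp) {
  if (p_severe_annual <= 0 || p_fatal_hosp <= 0)
    stop("p_severe_annual and p_fatal_hosp must be > 0")
  if (p_fatal_overall_annual < 0) stop("fatality target must be >= 0")
  p_fatal_overall_annual / (p_severe_annual * p_fatal_hosp)
}

#' Out-of-hospital fatality probability in the watchful-waiting state
#'
#' The per-day probability of food-allergy death while occupying the
#' watchful-waiting state, derived so that total annual food-allergy
#' fatality under watchful waiting equals the fatality multiplier times the
#' overall annual fatality probability. The in-hospital component (annual
#' reaction incidence x ED-visit probability x admission probability x
#' in-hospital fatality) is subtracted from that target and the remainder is
#' divided by the expected number of watchful-waiting state-days per
#' person-year (365 x daily reaction probability x fraction not transferred).
#'
#' @param params A `ww_parameters` object (the derived `p_ed_ww` must be set).
#' @return A list with `per_day` (per watchful-waiting day), `annual`
#'   (annualized form `1 - (1 - per_day)^365`, the reporting scale), and the
#'   intermediate `in_hospital_annual` component.
#' @export
derive_ww_out_of_hospital_fatality <- function(params) {
  e <- params$epi
  if (e$ww_fatality_multiplier < 1) stop("ww_fatality_multiplier must be >= 1")
  dpy <- params$settings$days_per_year
  target <- e$ww_fatality_multiplier * e$p_fatal_overall_annual
  in_hosp <- e$p_severe_annual * e$p_ed_ww * e$p_hosp_given_ed * e$p_fatal_hosp
  out <- target - in_hosp
  if (out < -1e-15)
    stop("invalid configuration: in-hospital fatality component (", in_hosp,
         ") exceeds the overall fatality target (", target, ")")
  out <- max(out, 0)
  p_react_daily <- annual_to_cycle_prob(e$p_severe_annual, dpy)
  ww_days_per_year <- dpy * p_react_daily * (1 - e$p_ed_ww)
  if (ww_days_per_year <= 0) {
    # everyone transfers: valid only if the target is fully met in hospital
    if (out > 1e-9 * max(target, 1e-300))
      stop("invalid configuration: no watchful-waiting exposure but ",
           "out-of-hospital fatality target is positive")
    q <- 0
  } else {
    q <- out / ww_days_per_year
  }
  if (q > 1) stop("invalid configuration: implied per-day fatality exceeds 1")
  list(per_day = q,
       annual = 1 - (1 - q)^dpy,
       in_hospital_annual = in_hosp)
}

#' Rescale the watchful-waiting fatality multiplier
#'
#' Returns a parameter set whose watchful-waiting out-of-hospital fatality is
#' re-derived with multiplier `k`; the immediate-transfer arm is untouched.
#'
#' @param params A `ww_parameters` object.
#' @param k New multiplier, at least 1.
#' @return The updated `ww_parameters` object.
#' @export
apply_fatality_multiplier <- function(params, k) {
  if (!is.finite(k) || k < 1) stop("fatality multiplier must be >= 1")
  params$epi$ww_fatality_multiplier <- k
  rederive_parameters(params)
}

#' @export
print.ww_parameters <- function(x, ...) {
  cat("Markov cohort parameters (watchful waiting vs immediate ED transfer)\n")
  cat(sprintf("  annual severe reaction: %.3f | ED visit if WW: %.3f\n",
              x$epi$p_severe_annual, x$epi$p_ed_ww))
  cat(sprintf("  WW fatality multiplier: %g (annualized out-of-hospital %.4g)\n",
              x$epi$ww_fatality_multiplier, x$epi$p_fa_ww_annual))
  cat(sprintf("  perspective: %s | discount %.1f%%/yr | horizon %d y | WTP %s/QALY\n",
              x$settings$perspective, 100 * x$settings$discount_rate_annual,
              x$settings$horizon_years,
              format(x$settings$wtp, big.mark = ",")))
  invisible(x)
}
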