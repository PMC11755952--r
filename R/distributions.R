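#' Probabilistic sensitivity analysis distributions
#'
#' The sampling distribution assigned to each uncertain parameter: beta for
#' probabilities and utilities, gamma (shape, scale) for costs and the ED
#' waiting time, and a lognormal (meanlog, sdlog) for hospital length of
#' stay. Parameters marked fixed in the source table (hospitalization
#' probability, fatality multiplier, autoinjector unit cost, in-ED injection
#' cost, hourly wage, hospitalization workday, annual remission cost) are not
#' sampled. The hospital daily cost is a ratio draw: a gamma total-stay cost
#' divided by a lognormal length of stay.
#'
#' @return A data.frame with columns `name`, `family`, `shape1`, `shape2`.
#'   For `beta`, shapes are (alpha, beta); for `gamma`, (shape, scale); for
#'   `lognormal`, (meanlog, sdlog); for `fixed`, `shape1` is the value.
#' @export
psa_distributions <- function() {
  spec <- rbind(
    c("p_severe_annual",         "beta",      66,    696),
    c("p_have_eai",              "beta",      8.5,   0.88),
    c("p_biphasic",              "beta",      184,   3806),
    c("p_fatal_overall_annual",  "beta",      100,   1.4e8),
    c("p_fatal_hosp",            "beta",      46,    1.0e4),
    c("p_remission_annual",      "beta",      47,    771),
    c("p_eai_before_ed",         "beta",      7.6,   6.5),
    c("ambulance_cost",          "gamma",     100,   8.5),
    c("ed_visit_medical_cost",   "gamma",     100,   3.0),
    c("ed_wait_hours",           "gamma",     0.27,  13),
    c("ed_oop_cost",             "gamma",     100,   0.89),
    c("hosp_total_cost",         "gamma",     100,   37),
    c("hosp_length_of_stay",     "lognormal", 0.25,  0.99),
    c("annual_fa_medical_cost",  "gamma",     100,   14),
    c("annual_fa_oop_cost",      "gamma",     100,   24),
    c("annual_fa_indirect_cost", "gamma",     100,   42),
    c("u_food_allergy",          "beta",      7.1,   0.62),
    c("disutility_reaction",     "beta",      0.17,  1.7),
    c("u_remission",             "beta",      8.8,   0.66)
  )
  data.frame(name = spec[, 1], family = spec[, 2],
             shape1 = as.numeric(spec[, 3]), shape2 = as.numeric(spec[, 4]))
}

#' Mean of a sampling distribution entry
#' @param family One of `"beta"`, `"gamma"`, `"lognormal"`, `"fixed"`.
#' @param shape1,shape2 Distribution parameters as in [psa_distributions()].
#' @return The distribution mean.
#' @export
distribution_mean <- function(family, shape1, shape2) {
  switch(family,
         beta = shape1 / (shape1 + shape2),
         gamma = shape1 * shape2,
         lognormal = exp(shape1 + shape2^2 / 2),
         fixed = shape1,
         stop("unknown distribution family: ", family))
}

draw_one <- function(family, shape1, shape2) {
  switch(family,
         beta = {
           if (shape1 <= 0 || shape2 <= 0) stop("beta shapes must be > 0")
           stats::rbeta(1, shape1, shape2)
         },
         gamma = {
           if (shape1 <= 0 || shape2 <= 0) stop("gamma shape/scale must be > 0")
           stats::rgamma(1, shape = shape1, scale = shape2)
         },
         lognormal = stats::rlnorm(1, meanlog = shape1, sdlog = shape2),
         fixed = shape1,
         stop("unknown distribution family: ", family))
}

# where each sampled quantity lands in the parameter object
.psa_assign <- list(
  p_severe_annual         = function(p, v) { p$epi$p_severe_annual <- v; p },
  p_have_eai              = function(p, v) { p$epi$p_no_eai <- 1 - v; p },
  p_biphasic              = function(p, v) { p$epi$p_biphasic <- v; p },
  p_fatal_overall_annual  = function(p, v) { p$epi$p_fatal_overall_annual <- v; p },
  p_fatal_hosp            = function(p, v) { p$epi$p_fatal_hosp <- v; p },
  p_remission_annual      = function(p, v) { p$epi$p_remission_annual <- v; p },
  p_eai_before_ed         = function(p, v) { p$cost$p_eai_before_ed <- v; p },
  ambulance_cost          = function(p, v) { p$cost$ambulance_cost <- v; p },
  ed_visit_medical_cost   = function(p, v) { p$cost$ed_visit_medical_cost <- v; p },
  ed_wait_hours           = function(p, v) { p$cost$ed_wait_hours <- v; p },
  ed_oop_cost             = function(p, v) { p$cost$ed_oop_cost <- v; p },
  annual_fa_medical_cost  = function(p, v) { p$cost$annual_fa_medical_cost <- v; p },
  annual_fa_oop_cost      = function(p, v) { p$cost$annual_fa_oop_cost <- v; p },
  annual_fa_indirect_cost = function(p, v) { p$cost$annual_fa_indirect_cost <- v; p },
  u_food_allergy          = function(p, v) { p$util$u_food_allergy <- v; p },
  disutility_reaction     = function(p, v) { p$util$disutility_reaction <- v; p },
  u_remission             = function(p, v) { p$util$u_remission <- v; p }
)

#' Draw one parameter set for probabilistic sensitivity analysis
#'
#' Samples every non-fixed parameter independently from its assigned
#' distribution using the current R random-number state, then re-derives all
#' dependent fields (ED-visit probability, immediate-arm epinephrine cost,
#' indirect visit costs, and the watchful-waiting out-of-hospital fatality,
#' whose annual target scales with the drawn overall fatality). The hospital
#' daily cost is the drawn total-stay cost divided by the drawn length of
#' stay.
#'
#' @param params Base `ww_parameters`; fixed fields are taken from here.
#' @param distributions A distribution table as from [psa_distributions()].
#' @return A new `ww_parameters` object.
#' @export
sample_psa_draw <- function(params, distributions = psa_distributions()) {
  hosp_total <- NA_real_
  hosp_los <- NA_real_
  for (i in seq_len(nrow(distributions))) {
    d <- distributions[i, ]
    v <- draw_one(d$family, d$shape1, d$shape2)
    if (d$name == "hosp_total_cost") {
      hosp_total <- v
    } else if (d$name == "hosp_length_of_stay") {
      hosp_los <- v
    } else {
      f <- .psa_assign[[d$name]]
      if (is.null(f)) stop("no assignment rule for sampled parameter '",
                           d$name, "'")
      params <- f(params, v)
    }
  }
  if (is.finite(hosp_total) && is.finite(hosp_los) && hosp_los > 0) {
    params$cost$hosp_daily_cost <- hosp_total / hosp_los
  }
  rederive_parameters(params)
}
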