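# shared fixtures built in code

# life table with constant (possibly zero) annual mortality
flat_life_table <- function(q = 0, max_age = 25) {
  synthetic_life_table(seed = 1, base_q = q, growth = 0, max_age = max_age)
}

# base parameters with the hospitalization probability set by the
# calibration identity, so that the out-of-hospital subtraction cancels
# exactly when everyone transfers to the ED
calibrated_parameters <- function(multiplier = 10) {
  p <- default_parameters()
  p$epi$p_hosp_given_ed <- calibrate_hospitalization_prob(
    p$epi$p_severe_annual, p$epi$p_fatal_overall_annual, p$epi$p_fatal_hosp)
  p$epi$ww_fatality_multiplier <- multiplier
  rederive_parameters(p)
}

# shorten the horizon (and start age if needed) for cheap runs
with_horizon <- function(params, years, start_age = params$settings$start_age_years) {
  params$settings$horizon_years <- years
  params$settings$start_age_years <- start_age
  params
}
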