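#' Deterministic base-case analysis
#'
#' Runs both strategies at the base-case parameter values and returns the
#' incremental comparison of watchful waiting against immediate ED transfer,
#' with the per-strategy results attached.
#'
#' @param params A `ww_parameters` object.
#' @param life_table A `life_table`.
#' @return A `ce_comparison` with extra components `watchful_waiting` and
#'   `immediate_ed` (the two `strategy_result`s).
#' @export
#' @examples
#' \donttest{
#' bc <- base_case(default_parameters(), bundled_life_table())
#' bc$delta_cost   # watchful waiting saves money (negative)
#' bc$icer         # CAD per QALY gained through immediate transfer
#' }
base_case <- function(params, life_table) {
  ww <- run_strategy("watchful_waiting", params, life_table)
  imm <- run_strategy("immediate_ed", params, life_table)
  cmp <- compare(imm, ww, params$settings$wtp)
  cmp$watchful_waiting <- ww
  cmp$immediate_ed <- imm
  cmp
}

# derived fields a DSA row may set directly, bypassing re-derivation
.derived_fields <- c("p_ed_ww", "epi_cost_immediate_ed", "ed_indirect_cost",
                     "hosp_indirect_cost", "p_fa_ww_daily")

set_param_field <- function(params, target, value, rederive = TRUE) {
  path <- strsplit(target, ".", fixed = TRUE)[[1]]
  if (length(path) != 2 || !path[1] %in% c("epi", "cost", "util", "settings"))
    stop("unknown parameter target '", target, "'")
  if (!path[2] %in% names(params[[path[1]]]))
    stop("unknown parameter field '", target, "'")
  params[[path[1]]][[path[2]]] <- value
  if (rederive)
    params <- rederive_parameters(
      params, keep = intersect(path[2], .derived_fields))
  params
}

#' Default one-way sensitivity-analysis grid
#'
#' The varied parameters and their bounds: plus or minus 20 percent of the
#' base value, at the rounding the source table reports them (e.g. 0.070
#' and 0.10 for the severe-reaction probability, 0.74 for the utility lower
#' bounds); utilities are capped at the 1.0 ceiling, and the ED epinephrine
#' cost spans its full logical range ($0.80, nobody uses an autoinjector at
#' home, to $95, everybody does). Bounds are stated for the default base
#' values; for non-default `params` the grid falls back to exact plus or
#' minus 20 percent.
#'
#' @param params A `ww_parameters` object supplying base values.
#' @return A data.frame with columns `parameter`, `target`, `low`, `high`.
#' @export
dsa_parameters <- function(params) {
  e <- params$epi; co <- params$cost; u <- params$util
  pm20 <- function(x) c(0.8 * x, 1.2 * x)
  # published rounded bounds, used when the base value is the default
  printed <- function(base, default, bounds) {
    if (isTRUE(all.equal(base, default))) bounds else pm20(base)
  }
  rows <- list(
    list("Annual probability of severe allergic reaction",
         "epi.p_severe_annual",
         printed(e$p_severe_annual, 0.087, c(0.070, 0.10))),
    list("Annual probability of food allergy remission",
         "epi.p_remission_annual",
         printed(e$p_remission_annual, 0.058, c(0.046, 0.070))),
    list("Probability of hospitalization following ED visit",
         "epi.p_hosp_given_ed", pm20(e$p_hosp_given_ed)),
    list("Probability of biphasic reaction",
         "epi.p_biphasic", printed(e$p_biphasic, 0.046, c(0.037, 0.055))),
    list("Food allergy fatality among hospitalized patients",
         "epi.p_fatal_hosp", printed(e$p_fatal_hosp, 0.0045,
                                     c(0.0036, 0.0054))),
    list("Epinephrine cost for immediate ED transfer",
         "cost.epi_cost_immediate_ed",
         c(co$ed_injection_cost, co$eai_unit_cost)),
    list("Ambulance cost", "cost.ambulance_cost",
         printed(co$ambulance_cost, 848, c(678, 1017))),
    list("Medical cost of ED visit", "cost.ed_visit_medical_cost",
         printed(co$ed_visit_medical_cost, 331, c(265, 397))),
    list("Daily medical cost of hospitalization", "cost.hosp_daily_cost",
         pm20(co$hosp_daily_cost)),
    list("Annual direct medical costs of food allergy",
         "cost.annual_fa_medical_cost",
         printed(co$annual_fa_medical_cost, 1388, c(1110, 1666))),
    list("Utility of food allergy", "util.u_food_allergy",
         printed(u$u_food_allergy, 0.92, c(0.74, 1.0))),
    list("Utility of food allergy remission", "util.u_remission",
         printed(u$u_remission, 0.93, c(0.74, 1.0))),
    list("Disutility of severe allergic reaction", "util.disutility_reaction",
         pm20(u$disutility_reaction))
  )
  data.frame(parameter = vapply(rows, `[[`, "", 1),
             target = vapply(rows, `[[`, "", 2),
             low = vapply(rows, function(r) r[[3]][1], 0),
             high = vapply(rows, function(r) r[[3]][2], 0))
}

clamp_bound <- function(value, target) {
  is_prob <- grepl("^epi\\.p_|^util\\.u_", target)
  if (is_prob && value > 1) {
    warning("bound ", value, " for ", target, " clamped to 1")
    value <- 1
  }
  if (value < 0) {
    warning("bound ", value, " for ", target, " clamped to 0")
    value <- 0
  }
  value
}

#' One-way deterministic sensitivity analysis
#'
#' For each parameter in `spec`, sets it to its lower then upper bound,
#' re-derives every dependent quantity (varying the biphasic probability
#' moves the ED-visit probability; varying any fatality input re-derives the
#' watchful-waiting out-of-hospital fatality against the fixed annual
#' target), reruns both strategies, and records the ICER at both bounds.
#' Rows are ordered by decreasing ICER range, giving the tornado ordering.
#'
#' @param params Base `ww_parameters`.
#' @param life_table A `life_table`.
#' @param spec A grid as from [dsa_parameters()].
#' @return A data.frame with columns `parameter`, `target`, `low`, `high`,
#'   `icer_low`, `icer_high`, `icer_range`, plus attribute `icer_base`.
#' @export
one_way_dsa <- function(params, life_table, spec = dsa_parameters(params)) {
  base <- base_case(params, life_table)
  icer_at <- function(target, value) {
    value <- clamp_bound(value, target)
    p <- set_param_field(params, target, value)
    validate_parameters(p)
    base_case(p, life_table)$icer
  }
  spec$icer_low <- mapply(icer_at, spec$target, spec$low)
  spec$icer_high <- mapply(icer_at, spec$target, spec$high)
  spec$icer_range <- abs(spec$icer_high - spec$icer_low)
  spec <- spec[order(-spec$icer_range), ]
  rownames(spec) <- NULL
  attr(spec, "icer_base") <- base$icer
  spec
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` parameter sets from the assigned distributions, runs both
#' strategies for each, and records the per-iteration strategy totals and
#' incremental outcomes (the cost-effectiveness plane). The point estimate
#' uses ratio-of-means: the ICER of the mean deltas, not the mean of
#' per-iteration ICERs. An iteration counts as cost-effective for watchful
#' waiting when its incremental net monetary benefit is positive at `wtp`.
#'
#' @param params Base `ww_parameters`.
#' @param life_table A `life_table`.
#' @param n Number of iterations.
#' @param seed Integer seed.
#' @param wtp Willingness to pay (defaults to the settings value).
#' @param distributions Distribution table, see [psa_distributions()].
#' @return A `psa_result` list: `iterations` (data.frame with per-iteration
#'   costs, QALYs, death risks and deltas), `n`, `seed`, `wtp`, the mean
#'   deltas, `icer` (of means), `inmb` (at mean deltas), and
#'   `frac_cost_effective`.
#' @export
run_psa <- function(params, life_table, n = 1000, seed = 1,
                    wtp = params$settings$wtp,
                    distributions = psa_distributions()) {
  stopifnot(n >= 1)
  set.seed(seed)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- sample_psa_draw(params, distributions)
    ww <- run_strategy("watchful_waiting", p, life_table)
    imm <- run_strategy("immediate_ed", p, life_table)
    rows[[i]] <- data.frame(
      iteration = i,
      cost_ww = ww$total_cost_discounted, qaly_ww = ww$total_qaly_discounted,
      cost_imm = imm$total_cost_discounted,
      qaly_imm = imm$total_qaly_discounted,
      fa_death_ww = ww$fa_death_risk, fa_death_imm = imm$fa_death_risk)
  }
  it <- do.call(rbind, rows)
  it$delta_cost <- it$cost_ww - it$cost_imm
  it$delta_qaly <- it$qaly_ww - it$qaly_imm
  it$delta_fa_death <- it$fa_death_ww - it$fa_death_imm
  it$inmb <- wtp * it$delta_qaly - it$delta_cost
  mean_dc <- mean(it$delta_cost)
  mean_dq <- mean(it$delta_qaly)
  structure(list(
    iterations = it, n = n, seed = seed, wtp = wtp,
    mean_delta_cost = mean_dc, mean_delta_qaly = mean_dq,
    icer = if (abs(mean_dq) > 0) mean_dc / mean_dq else NA_real_,
    inmb = wtp * mean_dq - mean_dc,
    frac_cost_effective = mean(it$inmb > 0)
  ), class = "psa_result")
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA iterations in
#' which watchful waiting has positive incremental net monetary benefit.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Numeric vector of willingness-to-pay thresholds.
#' @return A data.frame with columns `wtp` and `p_cost_effective`.
#' @export
ceac <- function(psa, wtp_grid) {
  it <- psa$iterations
  p <- vapply(wtp_grid,
              function(w) mean(w * it$delta_qaly - it$delta_cost > 0),
              0)
  data.frame(wtp = as.numeric(wtp_grid), p_cost_effective = p)
}

#' The seven scenario analyses
#'
#' Discount rates of 0 and 3 percent per year, the societal perspective,
#' 100-, 500- and 1,000-fold watchful-waiting fatality multipliers, and a
#' start age of zero years.
#'
#' @return A named list of override lists keyed by parameter target.
#' @export
scenario_specs <- function() {
  list(
    "0% discount rate"        = list("settings.discount_rate_annual" = 0),
    "3% discount rate"        = list("settings.discount_rate_annual" = 0.03),
    "Societal perspective"    = list("settings.perspective" = "societal"),
    "100-fold WW fatality"    = list("epi.ww_fatality_multiplier" = 100),
    "500-fold WW fatality"    = list("epi.ww_fatality_multiplier" = 500),
    "1000-fold WW fatality"   = list("epi.ww_fatality_multiplier" = 1000),
    "Starting age 0 years"    = list("settings.start_age_years" = 0)
  )
}

#' Run the scenario battery
#'
#' Applies each scenario's overrides to the base parameters (re-deriving
#' dependent fields), runs a PSA of `n` iterations with the same seed in
#' every scenario (common random numbers), and summarizes mean strategy
#' totals and incremental outcomes per scenario.
#'
#' @param params Base `ww_parameters`.
#' @param life_table A `life_table`.
#' @param specs Named list of scenarios, as [scenario_specs()].
#' @param n PSA iterations per scenario.
#' @param seed Integer seed reused across scenarios.
#' @return A data.frame, one row per scenario: mean total cost and QALYs per
#'   strategy, mean incremental cost and QALYs, ICER (ratio of means), and
#'   INMB at the scenario's willingness to pay.
#' @export
run_scenarios <- function(params, life_table, specs = scenario_specs(),
                          n = 1000, seed = 1) {
  out <- lapply(names(specs), function(nm) {
    p <- params
    for (key in names(specs[[nm]]))
      p <- set_param_field(p, key, specs[[nm]][[key]])
    validate_parameters(p)
    psa <- run_psa(p, life_table, n = n, seed = seed)
    it <- psa$iterations
    data.frame(scenario = nm,
               cost_ww = mean(it$cost_ww), cost_imm = mean(it$cost_imm),
               qaly_ww = mean(it$qaly_ww), qaly_imm = mean(it$qaly_imm),
               delta_cost = psa$mean_delta_cost,
               delta_qaly = psa$mean_delta_qaly,
               icer = psa$icer, inmb = psa$inmb,
               frac_cost_effective = psa$frac_cost_effective)
  })
  do.call(rbind, out)
}
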