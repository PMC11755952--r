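#' Per-state daily rewards for one strategy and perspective
#'
#' Builds the per-day cost and utility attached to each state. Because the
#' reaction-day states last exactly one cycle and have no self-transitions,
#' per-entry event costs (autoinjector replacement, ambulance, ED visit,
#' epinephrine, hospitalization day) are folded into those states' daily
#' cost. Baseline annual food-allergy costs accrue as a uniform daily share
#' on every alive pre-remission day; remission accrues its own annual cost
#' share. Utilities are annual health-state utilities divided over the year,
#' with the severe-reaction disutility applied on every day spent in a
#' reaction state (floored at zero).
#'
#' The epinephrine component of an ED entry is strategy-specific: the
#' immediate-transfer arm pays the blended in-ED plus expected pre-ED
#' autoinjector cost; under watchful waiting, ED arrivals are a mixture of
#' patients without an autoinjector (in-ED injection only) and biphasic
#' reactions (replacement autoinjector plus in-ED injection). The societal
#' perspective adds out-of-pocket and lost-productivity costs of ED visits
#' and hospitalization, and the annual out-of-pocket and indirect costs of
#' living with food allergy.
#'
#' @param strategy `"watchful_waiting"` or `"immediate_ed"`.
#' @param perspective `"healthcare"` or `"societal"`.
#' @param params A `ww_parameters` object.
#' @return A list with numeric 7-vectors `cost` (CAD per day in state) and
#'   `utility` (QALY accrued per day in state).
#' @export
cycle_rewards <- function(strategy, perspective, params) {
  strategy <- match.arg(strategy, c("watchful_waiting", "immediate_ed"))
  perspective <- match.arg(perspective, c("healthcare", "societal"))
  co <- params$cost; e <- params$epi; u <- params$util
  dpy <- params$settings$days_per_year
  societal <- perspective == "societal"

  base_daily <- co$annual_fa_medical_cost / dpy
  if (societal)
    base_daily <- base_daily +
      (co$annual_fa_oop_cost + co$annual_fa_indirect_cost) / dpy

  if (strategy == "immediate_ed") {
    epi_ed <- co$epi_cost_immediate_ed
  } else {
    w <- e$p_no_eai + e$p_biphasic
    epi_ed <- if (w > 0) {
      (e$p_no_eai * co$ed_injection_cost +
         e$p_biphasic * (co$eai_unit_cost + co$ed_injection_cost)) / w
    } else 0
  }
  ed_entry <- co$ambulance_cost + co$ed_visit_medical_cost + epi_ed
  if (societal) ed_entry <- ed_entry + co$ed_oop_cost + co$ed_indirect_cost
  hosp_day <- co$hosp_daily_cost
  if (societal) hosp_day <- hosp_day + co$hosp_indirect_cost

  cost <- c(no_reaction = base_daily,
            ww_reaction = base_daily + co$eai_unit_cost,
            ed_transfer = base_daily + ed_entry,
            hospitalization = base_daily + hosp_day,
            fa_death = 0,
            remission = co$annual_remission_medical_cost / dpy,
            all_cause_death = 0)

  u_react <- max(0, u$u_food_allergy - u$disutility_reaction)
  utility <- c(no_reaction = u$u_food_allergy,
               ww_reaction = u_react,
               ed_transfer = u_react,
               hospitalization = u_react,
               fa_death = 0,
               remission = u$u_remission,
               all_cause_death = 0) / dpy

  list(cost = cost, utility = utility)
}

#' Per-cycle discount factor
#'
#' Continuous per-cycle compounding of the annual rate:
#' `(1 + annual_rate)^(-cycle_index / days_per_year)`.
#'
#' @param cycle_index Cycle number (0 = model start).
#' @param annual_rate Annual discount rate, >= 0.
#' @param days_per_year Cycles per year (default 365).
#' @return Discount factor(s) in (0, 1].
#' @export
discount_factor <- function(cycle_index, annual_rate, days_per_year = 365) {
  stopifnot(annual_rate >= 0)
  (1 + annual_rate)^(-cycle_index / days_per_year)
}

#' Accumulate discounted costs and QALYs over a cohort trace
#'
#' Prices each cycle's occupancy with the per-state daily rewards, applies
#' the per-cycle discount factor, and sums over the horizon. Rewards accrue
#' on the post-transition occupancy of each cycle, so a reaction day is
#' priced in the cycle it is entered. The cumulative food-allergy death risk
#' is the terminal `fa_death` occupancy.
#'
#' @param trace A `cohort_trace` (or occupancy matrix with state columns).
#' @param rewards A reward list from [cycle_rewards()].
#' @param settings The `settings` component of a `ww_parameters` object.
#' @return A `strategy_result` list: `total_cost_discounted`,
#'   `total_qaly_discounted`, `total_cost_undiscounted`,
#'   `total_qaly_undiscounted`, `fa_death_risk`, `strategy`.
#' @export
accumulate <- function(trace, rewards, settings) {
  if (ncol(trace) != 7 || length(rewards$cost) != 7)
    stop("dimension mismatch between trace and rewards")
  tr_strat <- attr(trace, "strategy")
  cycles <- nrow(trace) - 1
  occ <- unclass(trace)[-1, , drop = FALSE]
  disc <- discount_factor(seq_len(cycles), settings$discount_rate_annual,
                          settings$days_per_year)
  cost_t <- as.numeric(occ %*% rewards$cost)
  qaly_t <- as.numeric(occ %*% rewards$utility)
  structure(list(
    total_cost_discounted = sum(disc * cost_t),
    total_qaly_discounted = sum(disc * qaly_t),
    total_cost_undiscounted = sum(cost_t),
    total_qaly_undiscounted = sum(qaly_t),
    fa_death_risk = unname(occ[cycles, "fa_death"]),
    strategy = if (is.null(tr_strat)) NA_character_ else tr_strat
  ), class = "strategy_result")
}

#' Run one strategy end to end
#'
#' Convenience wrapper: cohort trace, rewards under the settings'
#' perspective, and accumulation.
#'
#' @inheritParams build_transition_matrix
#' @return A `strategy_result`.
#' @export
run_strategy <- function(strategy, params, life_table) {
  trace <- run_cohort(strategy, params, life_table)
  rew <- cycle_rewards(strategy, params$settings$perspective, params)
  accumulate(trace, rew, params$settings)
}

#' Incremental cost-effectiveness comparison
#'
#' Deltas are comparator minus reference (watchful waiting versus immediate
#' ED transfer in the main analysis, so a negative incremental cost is a
#' saving). The ICER is computed from unrounded deltas; when the QALY delta
#' is (numerically) zero it is reported as `NA` with `dominance = TRUE`
#' rather than raising a division error. The incremental net monetary
#' benefit is `wtp * delta_qaly - delta_cost`, so comparator savings enter
#' positively.
#'
#' @param reference A `strategy_result` (immediate ED transfer).
#' @param comparator A `strategy_result` (watchful waiting).
#' @param wtp Willingness to pay, CAD per QALY.
#' @return A `ce_comparison` list: `delta_cost`, `delta_qaly`, `icer`,
#'   `inmb`, `delta_fa_death_risk`, `cost_per_death_prevented`, `dominance`,
#'   `wtp`.
#' @export
compare <- function(reference, comparator, wtp) {
  dc <- comparator$total_cost_discounted - reference$total_cost_discounted
  dq <- comparator$total_qaly_discounted - reference$total_qaly_discounted
  dfa <- comparator$fa_death_risk - reference$fa_death_risk
  dominance <- abs(dq) < .Machine$double.eps * 64
  structure(list(
    delta_cost = dc,
    delta_qaly = dq,
    icer = if (dominance) NA_real_ else dc / dq,
    inmb = wtp * dq - dc,
    delta_fa_death_risk = dfa,
    cost_per_death_prevented = if (abs(dfa) > 0) abs(dc) / abs(dfa) else NA_real_,
    dominance = dominance,
    wtp = wtp
  ), class = "ce_comparison")
}

#' @export
print.ce_comparison <- function(x, ...) {
  cat("Incremental comparison (comparator - reference)\n")
  cat(sprintf("  incremental cost:  $%s\n", format(round(x$delta_cost),
                                                   big.mark = ",")))
  cat(sprintf("  incremental QALYs: %.4g\n", x$delta_qaly))
  cat(sprintf("  ICER:              %s\n",
              if (is.na(x$icer)) "undefined (no QALY difference)"
              else paste0("$", format(round(x$icer), big.mark = ","), "/QALY")))
  cat(sprintf("  INMB at WTP $%s:  $%s\n", format(x$wtp, big.mark = ","),
              format(round(x$inmb), big.mark = ",")))
  cat(sprintf("  incremental food-allergy death risk: %.3g\n",
              x$delta_fa_death_risk))
  if (!is.na(x$cost_per_death_prevented))
    cat(sprintf("  cost per death prevented: $%s\n",
                format(round(x$cost_per_death_prevented), big.mark = ",")))
  invisible(x)
}
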