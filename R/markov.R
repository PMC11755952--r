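#' Health-state labels of the cohort model
#'
#' The seven states, in the canonical column order used by every matrix and
#' trace in the package. `fa_death` (food-allergy death) and
#' `all_cause_death` are absorbing.
#'
#' @return Character vector of length 7.
#' @export
state_space <- function() {
  c("no_reaction", "ww_reaction", "ed_transfer", "hospitalization",
    "fa_death", "remission", "all_cause_death")
}

#' Daily transition matrix at a given age
#'
#' Builds the 7x7 one-day transition matrix for one strategy and one integer
#' age. From `no_reaction`, all-cause mortality is allocated first; the
#' surviving mass splits between a severe reaction (routed entirely to
#' `ed_transfer` under immediate transfer, or split `p_ed_ww` to the ED and
#' the remainder to `ww_reaction` under watchful waiting), remission when the
#' age is inside the remission window, and staying put. The reaction-day
#' states last one cycle: `ww_reaction` resolves home or dies at the derived
#' per-day out-of-hospital fatality; `ed_transfer` admits with the
#' hospitalization probability; `hospitalization` lasts one additional day
#' with the in-hospital fatality risk. Food-allergy fatality is allocated
#' before all-cause death within reaction-day states; remission is absorbing
#' for allergy but not for background mortality.
#'
#' @param strategy `"watchful_waiting"` or `"immediate_ed"`.
#' @param age_years Integer age; must be covered by `life_table`.
#' @param params A `ww_parameters` object.
#' @param life_table A `life_table`.
#' @return A 7x7 row-stochastic matrix with state dimnames and attributes
#'   `age_years` and `strategy`.
#' @export
build_transition_matrix <- function(strategy, age_years, params, life_table) {
  strategy <- match.arg(strategy, c("watchful_waiting", "immediate_ed"))
  e <- params$epi
  dpy <- params$settings$days_per_year
  acm <- annual_to_cycle_prob(life_table_q(life_table, age_years), dpy)
  p_react <- annual_to_cycle_prob(e$p_severe_annual, dpy)
  in_window <- age_years >= e$remission_min_age & age_years <= e$remission_max_age
  p_rem <- if (in_window) annual_to_cycle_prob(e$p_remission_annual, dpy) else 0
  p_ed <- if (strategy == "immediate_ed") 1 else e$p_ed_ww
  q_ww <- e$p_fa_ww_daily

  s <- state_space()
  M <- matrix(0, 7, 7, dimnames = list(s, s))
  live <- 1 - acm
  # no_reaction
  M["no_reaction", "all_cause_death"] <- acm
  M["no_reaction", "ed_transfer"] <- live * p_react * p_ed
  M["no_reaction", "ww_reaction"] <- live * p_react * (1 - p_ed)
  M["no_reaction", "remission"] <- live * (1 - p_react) * p_rem
  M["no_reaction", "no_reaction"] <- live * (1 - p_react) * (1 - p_rem)
  # ww_reaction: out-of-hospital fatality first, then background mortality
  M["ww_reaction", "fa_death"] <- q_ww
  M["ww_reaction", "all_cause_death"] <- (1 - q_ww) * acm
  M["ww_reaction", "no_reaction"] <- (1 - q_ww) * live
  # ed_transfer
  M["ed_transfer", "all_cause_death"] <- acm
  M["ed_transfer", "hospitalization"] <- live * e$p_hosp_given_ed
  M["ed_transfer", "no_reaction"] <- live * (1 - e$p_hosp_given_ed)
  # hospitalization
  M["hospitalization", "fa_death"] <- e$p_fatal_hosp
  M["hospitalization", "all_cause_death"] <- (1 - e$p_fatal_hosp) * acm
  M["hospitalization", "no_reaction"] <- (1 - e$p_fatal_hosp) * live
  # remission: allergy-absorbing, background mortality still applies
  M["remission", "all_cause_death"] <- acm
  M["remission", "remission"] <- live
  # absorbing states
  M["fa_death", "fa_death"] <- 1
  M["all_cause_death", "all_cause_death"] <- 1

  rs <- rowSums(M)
  if (any(abs(rs - 1) > 1e-9))
    stop("internal consistency error: transition row sums deviate from 1 by ",
         max(abs(rs - 1)))
  structure(M, age_years = age_years, strategy = strategy)
}

transition_array <- function(strategy, params, life_table) {
  s <- params$settings
  ages <- s$start_age_years + seq_len(s$horizon_years) - 1
  arr <- vapply(ages, function(a)
    build_transition_matrix(strategy, a, params, life_table),
    matrix(0, 7, 7))
  list(array = arr, ages = ages)
}

#' Run the deterministic cohort trace
#'
#' Starts the full cohort in `no_reaction` at the configured start age and
#' propagates it through daily cycles over the horizon (age advances every
#' `days_per_year` cycles). The one-cycle reaction states have no
#' self-transitions, so their occupancy row equals the entry flow into them,
#' which is what the reward stage prices as per-event costs.
#'
#' @inheritParams build_transition_matrix
#' @return A `cohort_trace`: a `(cycles+1) x 7` occupancy matrix (row 0 is
#'   the initial distribution) with attributes `strategy`, `ages`,
#'   `days_per_year`.
#' @export
run_cohort <- function(strategy, params, life_table) {
  strategy <- match.arg(strategy, c("watchful_waiting", "immediate_ed"))
  s <- params$settings
  ages_needed <- s$start_age_years + c(0, s$horizon_years - 1)
  if (ages_needed[1] < min(life_table$age) || ages_needed[2] > max(life_table$age))
    stop("life table does not cover ages ", ages_needed[1], " to ",
         ages_needed[2])
  ta <- transition_array(strategy, params, life_table)
  cycles <- s$horizon_years * s$days_per_year
  init <- c(1, 0, 0, 0, 0, 0, 0)
  occ <- cohort_trace_cpp(as.numeric(ta$array), 7L, length(ta$ages), init,
                          as.integer(cycles), as.integer(s$days_per_year))
  colnames(occ) <- state_space()
  structure(occ, strategy = strategy, ages = ta$ages,
            days_per_year = s$days_per_year, class = c("cohort_trace", "matrix"))
}

#' Microsimulation oracle for the cohort trace
#'
#' Simulates `n_individuals` day by day with direct categorical draws from
#' the same per-age transition rows and returns the empirical occupancy
#' trace. This is the independent cross-check for [run_cohort()]: at modest
#' horizons the empirical occupancy must agree with the deterministic trace
#' within binomial Monte Carlo error.
#'
#' @inheritParams build_transition_matrix
#' @param n_individuals Number of simulated individuals.
#' @param seed Integer seed.
#' @param horizon_years Optional shorter horizon (defaults to the settings
#'   horizon).
#' @return A `(cycles+1) x 7` matrix of empirical occupancy fractions.
#' @export
microsim_cohort <- function(strategy, params, life_table, n_individuals,
                            seed, horizon_years = NULL) {
  stopifnot(n_individuals >= 1)
  if (!is.null(horizon_years)) params$settings$horizon_years <- horizon_years
  set.seed(seed)
  s <- params$settings
  ta <- transition_array(strategy, params, life_table)
  cycles <- s$horizon_years * s$days_per_year
  # per-year cumulative rows for inverse-CDF draws
  cums <- lapply(seq_along(ta$ages), function(y)
    t(apply(ta$array[, , y], 1, cumsum)))
  state <- rep.int(1L, n_individuals)
  occ <- matrix(0, cycles + 1, 7, dimnames = list(NULL, state_space()))
  occ[1, ] <- tabulate(state, 7) / n_individuals
  for (t in seq_len(cycles)) {
    y <- (t - 1) %/% s$days_per_year + 1
    cm <- cums[[min(y, length(cums))]]
    for (st in unique(state)) {
      if (st %in% c(5L, 7L)) next  # absorbing
      idx <- which(state == st)
      u <- stats::runif(length(idx))
      state[idx] <- findInterval(u, cm[st, ]) + 1L
    }
    occ[t + 1, ] <- tabulate(state, 7) / n_individuals
  }
  structure(occ, strategy = strategy, ages = ta$ages,
            days_per_year = s$days_per_year)
}

#' Export a cohort trace to CSV
#' @param trace A `cohort_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(cycle = seq_len(nrow(trace)) - 1, unclass(trace)[, ])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
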