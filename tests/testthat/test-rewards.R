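test_that("epinephrine component of an ED entry depends on the strategy", {
  p <- default_parameters()
  rw <- cycle_rewards("watchful_waiting", "healthcare", p)
  ri <- cycle_rewards("immediate_ed", "healthcare", p)
  base_daily <- p$cost$annual_fa_medical_cost / 365
  ed_fixed <- p$cost$ambulance_cost + p$cost$ed_visit_medical_cost
  # immediate arm: blended in-ED plus expected pre-ED autoinjector cost
  expect_equal(ri$cost[["ed_transfer"]] - base_daily - ed_fixed, 52.1)
  # watchful waiting: mixture of no-autoinjector and biphasic arrivals
  expect_equal(rw$cost[["ed_transfer"]] - base_daily - ed_fixed,
               (0.094 * 0.80 + 0.046 * 95.80) / 0.14, tolerance = 1e-12)
  # with no biphasic reactions only the in-ED injection is paid
  p0 <- p; p0$epi$p_biphasic <- 0; p0 <- rederive_parameters(p0)
  rw0 <- cycle_rewards("watchful_waiting", "healthcare", p0)
  expect_equal(rw0$cost[["ed_transfer"]] - base_daily - ed_fixed, 0.80)
  # home observation day pays the replacement autoinjector
  expect_equal(rw$cost[["ww_reaction"]] - base_daily, 95)
  expect_error(cycle_rewards("watchful_waiting", "welfare", p))
})

test_that("societal perspective adds out-of-pocket and productivity costs", {
  p <- default_parameters()
  hc <- cycle_rewards("immediate_ed", "healthcare", p)
  soc <- cycle_rewards("immediate_ed", "societal", p)
  extra_daily <- (p$cost$annual_fa_oop_cost + p$cost$annual_fa_indirect_cost) / 365
  expect_equal(soc$cost[["ed_transfer"]] - hc$cost[["ed_transfer"]],
               95 + 3.6 * 31.37 + extra_daily)
  expect_equal(soc$cost[["hospitalization"]] - hc$cost[["hospitalization"]],
               8 * 31.37 + extra_daily)
  expect_equal(soc$cost[["no_reaction"]] - hc$cost[["no_reaction"]],
               extra_daily)
  expect_equal(soc$utility, hc$utility)
})

test_that("reaction days carry the disutility and death states nothing", {
  rw <- cycle_rewards("watchful_waiting", "healthcare", default_parameters())
  expect_equal(rw$utility[["no_reaction"]], 0.92 / 365)
  expect_equal(rw$utility[["ww_reaction"]], (0.92 - 0.09) / 365)
  expect_equal(rw$utility[["hospitalization"]], (0.92 - 0.09) / 365)
  expect_equal(rw$utility[["remission"]], 0.93 / 365)
  expect_equal(rw$utility[["fa_death"]], 0)
  expect_equal(rw$cost[["all_cause_death"]], 0)
  expect_true(all(rw$utility >= 0 & rw$utility <= 1 / 365))
})

test_that("discounting follows per-cycle compounding of the annual rate", {
  expect_equal(discount_factor(0, 0.015), 1)
  expect_equal(discount_factor(365, 0.015), 1 / 1.015)
  expect_equal(discount_factor(c(100, 5000), 0), c(1, 1))
  expect_error(discount_factor(10, -0.01))
})

test_that("accumulation normalizes to one QALY per fully healthy year", {
  p <- default_parameters()
  p$epi$p_severe_annual <- 0
  p$epi$p_fatal_overall_annual <- 0
  p$epi$p_remission_annual <- 0
  p$settings$discount_rate_annual <- 0
  p <- with_horizon(rederive_parameters(p), 1, start_age = 10)
  trace <- run_cohort("watchful_waiting", p, flat_life_table(0))
  util <- c(1, 1, 1, 1, 0, 1, 0) / 365
  res <- accumulate(trace, list(cost = rep(0, 7), utility = util), p$settings)
  expect_equal(res$total_qaly_discounted, 1, tolerance = 1e-12)
  expect_equal(res$total_cost_discounted, 0)
})

test_that("discounted totals never exceed undiscounted and decrease in the rate", {
  lt <- bundled_life_table()
  totals <- lapply(c(0, 0.015, 0.03), function(r) {
    p <- default_parameters()
    p$settings$discount_rate_annual <- r
    run_strategy("watchful_waiting", p, lt)
  })
  costs <- vapply(totals, `[[`, 0, "total_cost_discounted")
  qalys <- vapply(totals, `[[`, 0, "total_qaly_discounted")
  expect_true(all(diff(costs) < 0))
  expect_true(all(diff(qalys) < 0))
  expect_equal(totals[[1]]$total_cost_discounted,
               totals[[1]]$total_cost_undiscounted)
  expect_lte(totals[[2]]$total_cost_discounted,
             totals[[2]]$total_cost_undiscounted)
  expect_lte(totals[[2]]$total_qaly_discounted,
             totals[[2]]$total_qaly_undiscounted)
})

test_that("comparison identities hold and degenerate deltas are flagged", {
  lt <- bundled_life_table()
  p <- default_parameters()
  ww <- run_strategy("watchful_waiting", p, lt)
  imm <- run_strategy("immediate_ed", p, lt)
  cmp <- compare(imm, ww, wtp = 50000)
  expect_equal(cmp$icer, cmp$delta_cost / cmp$delta_qaly, tolerance = 1e-9)
  expect_equal(cmp$inmb, 50000 * cmp$delta_qaly - cmp$delta_cost,
               tolerance = 1e-9)
  expect_equal(cmp$cost_per_death_prevented,
               abs(cmp$delta_cost) / abs(cmp$delta_fa_death_risk),
               tolerance = 1e-9)
  # watchful waiting saves money, loses QALYs, increases death risk
  expect_lt(cmp$delta_cost, 0)
  expect_lt(cmp$delta_qaly, 0)
  expect_gt(cmp$delta_fa_death_risk, 0)
  same <- compare(imm, imm, wtp = 50000)
  expect_equal(same$delta_cost, 0)
  expect_true(same$dominance)
  expect_true(is.na(same$icer))
})

test_that("with equal utilities and no disutility the QALY gap is pure mortality", {
  p <- default_parameters()
  p$util$disutility_reaction <- 0
  p$util$u_remission <- p$util$u_food_allergy
  lt <- bundled_life_table()
  ww <- run_strategy("watchful_waiting", p, lt)
  imm <- run_strategy("immediate_ed", p, lt)
  # discounted life-years via unit utility in every alive state
  ly <- function(strat) {
    trace <- run_cohort(strat, p, lt)
    util <- c(1, 1, 1, 1, 0, 1, 0) / 365
    accumulate(trace, list(cost = rep(0, 7), utility = util),
               p$settings)$total_qaly_discounted
  }
  dq <- ww$total_qaly_discounted - imm$total_qaly_discounted
  dly <- ly("watchful_waiting") - ly("immediate_ed")
  expect_equal(dq, p$util$u_food_allergy * dly, tolerance = 1e-10)
})
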