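test_that("base case collapses to zero deltas when strategies coincide", {
  p <- calibrated_parameters(multiplier = 1)
  p$epi$p_no_eai <- 1
  p <- rederive_parameters(p)
  bc <- base_case(p, bundled_life_table())
  expect_equal(bc$delta_qaly, 0, tolerance = 1e-12)
  expect_equal(bc$delta_fa_death_risk, 0, tolerance = 1e-15)
  expect_true(bc$dominance)
  # cost deltas differ only through the epinephrine mixture at the ED,
  # which the two arms price differently even with identical traces
  expect_lt(abs(bc$delta_cost), 100)
})

test_that("a parameter with no pathway leaves the ICER unchanged", {
  p <- default_parameters()
  p$epi$p_remission_annual <- 0
  p <- rederive_parameters(p)
  spec <- data.frame(parameter = "remission utility",
                     target = "util.u_remission", low = 0.74, high = 1.0)
  dsa <- one_way_dsa(p, bundled_life_table(), spec)
  expect_equal(dsa$icer_low, dsa$icer_high)
})

test_that("the ICER rises with every cost in the avoided ED bundle", {
  dsa <- one_way_dsa(default_parameters(), bundled_life_table())
  for (tg in c("cost.ambulance_cost", "cost.ed_visit_medical_cost",
               "cost.epi_cost_immediate_ed")) {
    row <- dsa[dsa$target == tg, ]
    expect_lt(row$icer_low, row$icer_high)
  }
  # out-of-domain bounds are clamped with a warning
  spec <- data.frame(parameter = "utility", target = "util.u_food_allergy",
                     low = 0.9, high = 1.15)
  expect_warning(one_way_dsa(default_parameters(), bundled_life_table(), spec),
                 "clamped")
})

test_that("point-mass distributions reproduce the base parameters", {
  base <- default_parameters()
  d <- psa_distributions()
  d$family <- "fixed"
  flat <- flatten_parameters(base)
  for (i in seq_len(nrow(d))) {
    d$shape1[i] <- switch(d$name[i],
                          p_have_eai = 1 - base$epi$p_no_eai,
                          hosp_total_cost = base$cost$hosp_daily_cost * 2,
                          hosp_length_of_stay = 2,
                          flat[[d$name[i]]])
  }
  drawn <- sample_psa_draw(base, d)
  expect_equal(drawn, base)
})

test_that("sampled parameters have the published distributional structure", {
  base <- default_parameters()
  set.seed(11)
  n <- 10000
  bip <- replicate(n, sample_psa_draw(base)$epi$p_biphasic)
  m <- 184 / (184 + 3806)
  se <- sqrt(m * (1 - m) / (184 + 3806 + 1)) / sqrt(n)
  expect_lt(abs(mean(bip) - m), 3 * se)
  # identical seed, identical draw
  set.seed(4); a <- sample_psa_draw(base)
  set.seed(4); b <- sample_psa_draw(base)
  expect_identical(a, b)
})

test_that("PSA is seed-reproducible and n = 1 matches a single draw", {
  p <- default_parameters()
  lt <- bundled_life_table()
  r1 <- run_psa(p, lt, n = 5, seed = 31)
  r2 <- run_psa(p, lt, n = 5, seed = 31)
  expect_identical(r1$iterations, r2$iterations)
  one <- run_psa(p, lt, n = 1, seed = 17)
  set.seed(17)
  pd <- sample_psa_draw(p)
  ww <- run_strategy("watchful_waiting", pd, lt)
  imm <- run_strategy("immediate_ed", pd, lt)
  expect_equal(one$iterations$delta_cost,
               ww$total_cost_discounted - imm$total_cost_discounted)
  expect_equal(one$iterations$delta_qaly,
               ww$total_qaly_discounted - imm$total_qaly_discounted)
})

test_that("PSA means agree across independent seeds within sampling error", {
  p <- default_parameters()
  lt <- bundled_life_table()
  a <- run_psa(p, lt, n = 40, seed = 1001)
  b <- run_psa(p, lt, n = 40, seed = 2002)
  se <- sqrt(stats::var(a$iterations$delta_cost) / a$n +
               stats::var(b$iterations$delta_cost) / b$n)
  expect_lt(abs(a$mean_delta_cost - b$mean_delta_cost), 3 * se)
})

test_that("the acceptability curve is a recount of stored iterations", {
  p <- default_parameters()
  psa <- run_psa(p, bundled_life_table(), n = 30, seed = 8)
  grid <- c(0, 25000, 50000, 100000, 150000)
  curve <- ceac(psa, grid)
  # brute-force recount, iteration by iteration
  brute <- vapply(grid, function(w) {
    ok <- 0
    for (i in seq_len(psa$n)) {
      it <- psa$iterations[i, ]
      if (w * it$delta_qaly - it$delta_cost > 0) ok <- ok + 1
    }
    ok / psa$n
  }, 0)
  expect_equal(curve$p_cost_effective, brute)
  # all QALY deltas share a sign, so the curve is monotone in WTP
  expect_true(all(psa$iterations$delta_qaly < 0))
  expect_true(all(diff(curve$p_cost_effective) <= 0))
  expect_equal(nrow(ceac(psa, numeric(0))), 0)
})

test_that("zero discounting makes discounted and undiscounted totals equal", {
  p <- default_parameters()
  p$settings$discount_rate_annual <- 0
  bc <- base_case(p, bundled_life_table())
  expect_equal(bc$watchful_waiting$total_cost_discounted,
               bc$watchful_waiting$total_cost_undiscounted)
  expect_equal(bc$immediate_ed$total_qaly_discounted,
               bc$immediate_ed$total_qaly_undiscounted)
})

test_that("watchful waiting loses value as the fatality multiplier grows", {
  lt <- bundled_life_table()
  base <- default_parameters()
  inmb <- vapply(c(10, 100, 500, 1000), function(k) {
    base_case(apply_fatality_multiplier(base, k), lt)$inmb
  }, 0)
  expect_true(all(diff(inmb) < 0))
})

test_that("scenario overrides are applied and unknown keys rejected", {
  expect_error(run_scenarios(default_parameters(), bundled_life_table(),
                             specs = list(bad = list("epi.no_such" = 1)),
                             n = 1, seed = 1),
               "no_such")
  sc <- run_scenarios(default_parameters(), bundled_life_table(),
                      specs = scenario_specs()[c("0% discount rate",
                                                 "Societal perspective")],
                      n = 3, seed = 5)
  expect_equal(nrow(sc), 2)
  # societal perspective books more spending on both strategies
  expect_gt(sc$cost_ww[2], sc$cost_ww[1] * 2)
})
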