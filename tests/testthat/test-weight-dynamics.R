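test_that("baseline fat regression behaves anthropometrically", {
  f_m <- baseline_fat_mass("male", 35, 1.70, 70)
  f_f <- baseline_fat_mass("female", 35, 1.70, 70)
  expect_gt(f_f, f_m)
  # frozen hand evaluation of the regression for the reference man:
  # (0.14*35 + 37.31*ln(70/1.7^2) - 103.94)/100 * 70
  bmi <- 70 / 1.7^2
  expect_equal(f_m, (0.14 * 35 + 37.31 * log(bmi) - 103.94) / 100 * 70)
  expect_equal(f_m, 13.91311, tolerance = 1e-5)
  # monotone in BMI at fixed sex/age/height
  f_ob <- baseline_fat_mass("male", 35, 1.70, 35 * 1.7^2)
  f_nm <- baseline_fat_mass("male", 35, 1.70, 22 * 1.7^2)
  expect_gt(f_ob / (35 * 1.7^2), f_nm / (22 * 1.7^2))
  # implausible prediction is clamped with a warning
  expect_warning(f_lo <- baseline_fat_mass("male", 20, 2.0, 45), "clamped")
  expect_equal(f_lo, 0.05 * 45)
})

test_that("steady-state calibration zeroes the baseline energy residual", {
  p <- calibrate_steady_state(ref_adult(), model_params())
  expect_lt(attr(p, "residual"), 1e-6)
  expect_false(is.na(p$k_expenditure))

  # intake shift at fixed anthropometry moves k by exactly the difference
  ind2 <- ref_adult()
  ind2$tei_init <- 2 * ind2$tei_init
  p2 <- calibrate_steady_state(ind2, model_params())
  expect_equal(p2$k_expenditure - p$k_expenditure, ref_adult()$tei_init)

  pop <- small_pop(n = 80, seed = 41)
  for (i in seq_len(nrow(pop))) {
    expect_lt(attr(calibrate_steady_state(pop[i, ], model_params()),
                   "residual"), 1e-6)
  }
  bad <- ref_adult(); bad$tei_init <- -10
  expect_error(calibrate_steady_state(bad), "ref")
})

test_that("a calibrated individual stays at steady state for 12 years", {
  pop <- small_pop(n = 150, seed = 42)
  res <- simulate_cohort(pop, policy_scenario(target = 0), model_params())
  expect_lt(max(abs(res$delta_weight)), 0.01)
})

test_that("full compensation produces exactly zero weight change", {
  pop <- small_pop(n = 60, seed = 43)
  res <- simulate_cohort(pop, policy_scenario(compensation = 100))
  expect_equal(max(abs(res$delta_weight)), 0)
})

test_that("long-run response matches the Forbes-curve root-finding oracle", {
  p <- model_params()
  for (case in list(list(ind = ref_adult(), dei = -100),
                    list(ind = within(ref_adult(), {
                      sex <- "female"; weight <- 85; height <- 1.58
                      tei_init <- 2100
                    }), dei = -60))) {
    ind <- as.data.frame(case$ind)
    sim <- simulate_weight(ind, constant_trajectory(case$dei, 40), p)
    oracle <- oracle_steady_delta_weight(ind, case$dei, p)
    expect_equal(sim$delta_weight, oracle, tolerance = 0.05)
  }
})

test_that("energy is conserved along the integration", {
  pop <- small_pop(n = 40, seed = 44)
  res <- simulate_cohort(pop, policy_scenario(compensation = 0))
  s0 <- attr(res, "state_baseline")
  sT <- attr(res, "state_final")
  p <- model_params()
  lhs <- p$rho_f * (sT$fat - s0$fat) + p$rho_l * (sT$lean - s0$lean) +
    p$rho_g * (sT$glycogen - s0$glycogen)
  rhs <- attr(res, "energy_integral")
  # tolerance: integrator error times a safety factor, relative to the
  # ~1e7 kcal cumulative intake over 12 years
  expect_lt(max(abs(lhs - rhs)), 1)
})

test_that("larger intake cuts never produce less weight loss", {
  pop <- small_pop(n = 30, seed = 45)
  prev <- rep(0, nrow(pop))
  for (target in c(0.25, 0.5, 0.75, 1)) {
    res <- simulate_cohort(pop, policy_scenario(target = target,
                                                compensation = 0))
    expect_true(all(res$delta_weight <= prev + 1e-9))
    prev <- res$delta_weight
  }
})

test_that("halving the integration step leaves final weight unchanged", {
  pop <- small_pop(n = 25, seed = 46)
  r1 <- simulate_cohort(pop, policy_scenario(), model_params(step_days = 1))
  r2 <- simulate_cohort(pop, policy_scenario(),
                        model_params(step_days = 0.5))
  expect_lt(max(abs(r1$delta_weight - r2$delta_weight)), 1e-3)
})

test_that("the rollout-shape scenarios converge two years after rollout", {
  pop <- small_pop(n = 150, seed = 47)
  w <- pop$survey_weight
  dw <- vapply(c("decreasing", "constant", "increasing"), function(s) {
    res <- simulate_cohort(pop, policy_scenario(scenario = s))
    weighted.mean(res$delta_weight, w)
  }, numeric(1))
  expect_lt(max(dw) - min(dw), 0.02)

  # the two-year lag transient is material: year 12 differs from year 10
  res <- simulate_cohort(pop, policy_scenario())
  snap <- attr(res, "snapshot_weight")
  yrs <- attr(res, "snapshot_years")
  w10 <- snap[, yrs == 10]; w12 <- snap[, yrs == 12]
  expect_gt(abs(weighted.mean(w12 - w10, w)), 0.05)
})

test_that("single-individual and cohort engines agree", {
  ind <- ref_adult()
  sc <- policy_scenario(compensation = 43)
  tr <- build_trajectory(ind, reduction_schedule(0.5, 10), sc)
  sim1 <- simulate_weight(ind, tr, model_params())
  res <- simulate_cohort(ind, sc, model_params())
  expect_equal(sim1$delta_weight, res$delta_weight, tolerance = 5e-3)
  expect_equal(length(sim1$days), 365 * 12 + 1)
  expect_true(all(sim1$weight > 0))
})

test_that("disabling the fluid sub-model isolates the fat-lean core", {
  pop <- small_pop(n = 20, seed = 48)
  p <- model_params(fluid_compartments = FALSE)
  res <- simulate_cohort(pop, policy_scenario(compensation = 0), p)
  sT <- attr(res, "state_final"); s0 <- attr(res, "state_baseline")
  expect_equal(sT$glycogen, s0$glycogen)
  expect_equal(sT$ecf, s0$ecf)
  expect_true(all(res$delta_weight[pop$sugar_ssb > 0] < 0))
})
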