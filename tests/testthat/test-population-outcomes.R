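test_that("BMI classification uses half-open WHO boundaries", {
  expect_equal(as.character(classify_bmi(c(17, 24.999, 25, 29.999, 30, 42))),
               c("normal", "normal", "overweight", "overweight",
                 "obese", "obese"))
  expect_error(classify_bmi(0), "positive")
  expect_error(classify_bmi(-3), "positive")
})

test_that("case projection is a signed pp-to-persons rescaling", {
  expect_equal(project_cases(-3.9, 9e7), -3510000)
  expect_equal(project_cases(0, 5e7), 0)
  expect_equal(project_cases(3.8, 92.1e6), 3499800)
  expect_error(project_cases(1, -1), "projected_adults")
})

make_results <- function(pop, new_bmi) {
  data.frame(id = pop$id,
             weight0 = pop$weight,
             weight_final = new_bmi * pop$height^2,
             delta_weight = new_bmi * pop$height^2 - pop$weight,
             bmi0 = pop$weight / pop$height^2,
             bmi_final = new_bmi,
             delta_bmi = new_bmi - pop$weight / pop$height^2,
             delta_sugar = -0.5 * pop$sugar_ssb,
             delta_intake = -0.285 * pop$sugar_ssb,
             stringsAsFactors = FALSE)
}

test_that("weighted summary reproduces hand-computed weighted means", {
  pop <- toy_population()[1:2, ]
  pop$survey_weight <- c(1, 3)
  res <- make_results(pop, pop$weight / pop$height^2)
  res$delta_weight <- c(-1, -2)
  out <- weighted_summary(pop, res, strata = "overall",
                          ci_method = "linearization")
  expect_equal(out$means$mean_delta_weight, -1.75)
  # the generic estimator agrees with a brute-force loop on a seeded pop
  bigpop <- small_pop(n = 150, seed = 55)
  bres <- make_results(bigpop, bigpop$weight / bigpop$height^2)
  out2 <- weighted_summary(bigpop, bres, strata = "overall",
                           ci_method = "linearization")
  expect_equal(out2$means$mean_delta_sugar,
               sum(bigpop$survey_weight * bres$delta_sugar) /
                 sum(bigpop$survey_weight))
})

test_that("prevalence accounting is exact on a constructed crossing", {
  # 30% of the weight mass crosses the obesity boundary downward
  pop <- toy_population()
  pop$survey_weight <- c(3, 3, 3, 1)
  h <- pop$height
  pop$weight <- c(31, 31, 26, 22) * h^2          # baseline: a,b obese-ish
  base_bmi <- c(31, 31, 26, 22)
  new_bmi <- c(29.5, 31, 26, 22)                 # only "a" crosses 30
  res <- make_results(pop, new_bmi)
  out <- weighted_summary(pop, res, strata = "overall",
                          ci_method = "linearization")
  pv <- out$prevalence
  expect_equal(pv$delta_pp[pv$category == "obese"], -30)
  expect_equal(pv$delta_pp[pv$category == "overweight"], 30)
  expect_equal(sum(pv$delta_pp), 0, tolerance = 1e-9)
  expect_equal(sum(pv$prev_baseline), 1, tolerance = 1e-9)
  expect_equal(sum(pv$prev_final), 1, tolerance = 1e-9)
  # relative change and cases follow from the pp change
  expect_equal(pv$delta_relative[pv$category == "obese"], -30 / 0.6)
  expect_equal(pv$cases_millions[pv$category == "obese"],
               project_cases(-30, 9e7) / 1e6)
})

test_that("bootstrap and linearization give comparable interval widths", {
  pop <- small_pop(n = 250, seed = 51)
  res <- make_results(pop, pop$weight / pop$height^2 - 0.5)
  out_b <- weighted_summary(pop, res, strata = "overall", n_boot = 200,
                            boot_seed = 7)
  out_l <- weighted_summary(pop, res, strata = "overall",
                            ci_method = "linearization")
  se_b <- (out_b$means$mean_delta_intake_hi -
             out_b$means$mean_delta_intake_lo) / (2 * 1.96)
  se_l <- (out_l$means$mean_delta_intake_hi -
             out_l$means$mean_delta_intake_lo) / (2 * 1.96)
  expect_gt(se_b, 0)
  expect_lt(abs(se_b - se_l) / se_l, 0.5)
  # same point estimates either way
  expect_equal(out_b$means$mean_delta_weight, out_l$means$mean_delta_weight)
})

test_that("stratified summaries cover all strata and conserve categories", {
  pop <- small_pop(n = 200, seed = 52)
  res <- make_results(pop, (pop$weight / pop$height^2) * 0.985)
  out <- weighted_summary(pop, res, n_boot = 50, boot_seed = 3)
  expect_setequal(unique(out$means$stratum_var),
                  c("overall", "sex", "age_group", "ses"))
  for (key in unique(paste(out$prevalence$stratum_var,
                           out$prevalence$stratum))) {
    rows <- paste(out$prevalence$stratum_var, out$prevalence$stratum) == key
    expect_equal(sum(out$prevalence$delta_pp[rows]), 0, tolerance = 1e-9)
  }
  # population shares sum to 1 within each stratification variable
  for (sv in c("sex", "age_group", "ses")) {
    expect_equal(sum(out$means$pop_share[out$means$stratum_var == sv]), 1,
                 tolerance = 1e-12)
  }
})

test_that("consumers-only summaries show larger mean weight loss", {
  pop <- small_pop(n = 300, seed = 53)
  sc <- policy_scenario(years = 3, horizon_years = 4)
  res <- simulate_cohort(pop, sc)
  all_out <- weighted_summary(pop, res, strata = "overall",
                              ci_method = "linearization")
  cons_out <- weighted_summary(pop, res, strata = "overall",
                               consumers_only = TRUE,
                               ci_method = "linearization")
  expect_lt(cons_out$means$mean_delta_weight,
            all_out$means$mean_delta_weight)
})

test_that("design-based CIs cover the configured mean at nominal rate", {
  hits <- 0
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    cfg <- population_config(n_records = 200, seed = 1000 + r)
    pop <- generate_population(cfg)
    m <- weighted.mean(pop$sugar_total, pop$survey_weight)
    se <- ssbreform:::linearized_se(pop$sugar_total, pop$survey_weight,
                                    pop$stratum, pop$psu)
    df <- length(unique(paste(pop$stratum, pop$psu))) -
      length(unique(pop$stratum))
    q <- qt(0.975, df)
    lo <- m - q * se; hi <- m + q * se
    if (lo <= 244.9 && 244.9 <= hi) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.90)
  expect_lte(hits / n_rep, 0.99)
})

test_that("sensitivity matrix is monotone with exact boundary rows", {
  pop <- small_pop(n = 40, seed = 54)
  m <- sensitivity_matrix(pop, targets = c(0, 0.5, 1),
                          compensations = c(0, 50, 100),
                          years = 3, horizon_years = 3)
  expect_equal(dim(m), c(3L, 3L))
  expect_true(all(m[, "0%"] == 0))          # no policy, no change
  expect_true(all(m["100%", ] == 0))        # full compensation null
  # more reduction never less loss; more compensation never more loss
  expect_true(all(diff(t(m)) <= 1e-9))
  expect_true(all(diff(m) >= -1e-9))
  # cell-by-cell re-run oracle
  sc <- policy_scenario(target = 0.5, compensation = 50, years = 3,
                        horizon_years = 3)
  res <- simulate_cohort(pop, sc)
  expect_equal(m["50%", "50%"],
               weighted.mean(res$delta_weight, pop$survey_weight),
               tolerance = 1e-12)
})
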