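# shared fixtures: built in code, deterministic given the stated seeds

ref_adult <- function() {
  data.frame(id = "ref", sex = "male", age = 35, height = 1.70, weight = 70,
             ses = "middle", tei_init = 2400, sugar_total = 250,
             sugar_ssb = 100, sugar_other = 150, survey_weight = 1,
             stratum = 1L, psu = 1L, stringsAsFactors = FALSE)
}

# a tiny hand-built population covering consumers, a non-consumer and a
# high-"others" (full-removal) individual, with unequal weights
toy_population <- function() {
  data.frame(
    id = c("a", "b", "c", "d"),
    sex = c("male", "female", "male", "female"),
    age = c(25, 45, 65, 30),
    height = c(1.70, 1.55, 1.65, 1.60),
    weight = c(70, 80, 60, 95),
    ses = c("low", "middle", "high", "middle"),
    tei_init = c(2000, 1800, 2200, 2500),
    sugar_total = c(300, 150, 400, 0),
    sugar_ssb = c(150, 0, 100, 0),
    sugar_other = c(150, 150, 300, 0),
    survey_weight = c(2, 1, 3, 4),
    stratum = c(1L, 1L, 2L, 2L),
    psu = c(1L, 2L, 3L, 4L),
    stringsAsFactors = FALSE
  )
}

small_pop <- function(n = 120, seed = 11) {
  generate_population(population_config(n_records = n, seed = seed))
}

# constant-step intake trajectory (net == carbohydrate change), for
# driving simulate_weight outside any schedule
constant_trajectory <- function(delta, years) {
  n <- 365 * years
  structure(data.frame(day = 0:n,
                       delta_intake = c(0, rep(delta, n)),
                       delta_carb = c(0, rep(delta, n))),
            class = c("ssb_trajectory", "data.frame"))
}

# independent long-run oracle: solve for the post-intervention steady
# state on the Forbes curve by root-finding, using quasi-static glycogen,
# fluid and adaptive-thermogenesis limits
oracle_steady_delta_weight <- function(ind, delta_ei, params) {
  st <- ssbreform:::baseline_body_state(ind, params)
  delta <- ssbreform:::activity_coefficient(ind, params)
  k <- calibrate_steady_state(ind, params)$k_expenditure
  ci_b <- params$carb_share * ind$tei_init
  d_ci <- if (params$carb_accounting == "net") {
    params$carb_fraction * delta_ei
  } else {
    delta_ei
  }
  ci_star <- max(ci_b + d_ci, 0)
  g_star <- params$glycogen_init * sqrt(ci_star / ci_b)
  ecf_star <- st$ecf +
    params$xi_ci * (ci_star - ci_b) / (ci_b * params$xi_na)
  lean_of_fat <- function(f) {
    st$lean + (params$rho_f / params$rho_l) * params$forbes_c *
      log(f / st$fat)
  }
  balance <- function(f) {
    l <- lean_of_fat(f)
    bw <- f + l + g_star * (1 + params$hydration_ratio) + ecf_star
    k + params$gamma_f * f + params$gamma_l * l + delta * bw +
      params$beta_tef * delta_ei + params$beta_at * delta_ei -
      (ind$tei_init + delta_ei)
  }
  f_star <- uniroot(balance, c(0.5, st$fat * 2), tol = 1e-10)$root
  f_star + lean_of_fat(f_star) +
    g_star * (1 + params$hydration_ratio) + ecf_star - ind$weight
}
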