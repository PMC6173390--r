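#' Baseline body-fat mass from anthropometry
#'
#' Predicts initial fat mass from sex, age and BMI with the ln(BMI)
#' body-fat-percent regressions used by the adult dynamic weight-model
#' family: `%fat = 0.14 * age + 37.31 * ln(BMI) - 103.94` for men and
#' `0.14 * age + 39.96 * ln(BMI) - 102.01` for women. Predictions outside
#' `bounds` (fractions of body weight) are clamped with a warning.
#'
#' @param sex `"male"` or `"female"` (vectorized).
#' @param age years.
#' @param height m.
#' @param weight kg.
#' @param bounds admissible fat fraction range. Default `c(0.05, 0.60)`.
#' @return fat mass, kg.
#' @export
#' @examples
#' baseline_fat_mass("male", 35, 1.70, 70)
#' baseline_fat_mass("female", 35, 1.70, 70)  # higher, as expected
baseline_fat_mass <- function(sex, age, height, weight,
                              bounds = c(0.05, 0.60)) {
  if (any(height <= 0) || any(weight <= 0)) {
    stop_domain("height and weight must be positive")
  }
  bmi <- weight / height^2
  pct <- ifelse(sex == "male",
                0.14 * age + 37.31 * log(bmi) - 103.94,
                0.14 * age + 39.96 * log(bmi) - 102.01) / 100
  out_of_range <- pct < bounds[1] | pct > bounds[2]
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " fat-fraction prediction(s) outside [",
            bounds[1], ", ", bounds[2], "] were clamped")
    pct <- pmin(pmax(pct, bounds[1]), bounds[2])
  }
  pct * weight
}

# Mifflin-St Jeor resting metabolic rate, kcal/day
mifflin_rmr <- function(sex, age, height, weight) {
  10 * weight + 6.25 * (100 * height) - 5 * age +
    ifelse(sex == "male", 5, -161)
}

# physical-activity expenditure coefficient delta (kcal/kg/day): the
# activity cost is delta * current body weight
activity_coefficient <- function(population, params) {
  if (!is.null(params$delta_activity)) {
    return(rep(params$delta_activity, nrow(population)))
  }
  rmr <- mifflin_rmr(population$sex, population$age, population$height,
                     population$weight)
  pmax(0, ((1 - params$beta_tef) * params$pal - 1) * rmr / population$weight)
}

# initial compartment masses for every individual; lean tissue is the
# residual after fat, glycogen (with bound water) and extracellular fluid
baseline_body_state <- function(population, params) {
  fat <- baseline_fat_mass(population$sex, population$age,
                           population$height, population$weight,
                           bounds = params$fat_bounds)
  glycogen <- rep(params$glycogen_init, nrow(population))
  ecf <- params$ecf_fraction * population$weight
  lean <- population$weight - fat -
    glycogen * (1 + params$hydration_ratio) - ecf
  if (any(lean <= 0)) {
    bad <- population$id[lean <= 0]
    stop_domain("non-positive lean mass implied for: ",
                paste(utils::head(bad, 5), collapse = ", "))
  }
  data.frame(fat = fat, lean = lean, glycogen = glycogen, ecf = ecf)
}

#' Calibrate an individual's expenditure constant to baseline steady state
#'
#' The model assumes each individual starts in energy balance: total
#' expenditure equals reported baseline intake. At the initial body
#' composition with no intake change, expenditure reduces to
#' `k + gamma_f * F0 + gamma_l * L0 + delta * W0` (`delta` the
#' physical-activity coefficient), so the individual constant is
#' `k = tei_init - gamma_f * F0 - gamma_l * L0 - delta * W0` in closed
#' form; the calibration residual is zero to machine precision.
#'
#' @param individual one-row `data.frame` (or list) with `sex`, `age`,
#'   `height`, `weight` and `tei_init` (and `id` for error messages).
#' @param params [model_params()].
#' @return `params` with `k_expenditure` set; attribute `"residual"`
#'   holds `|intake - expenditure|` at baseline.
#' @export
#' @examples
#' ind <- data.frame(id = "x", sex = "male", age = 35, height = 1.7,
#'                   weight = 70, tei_init = 2400)
#' p <- calibrate_steady_state(ind, model_params())
#' p$k_expenditure
calibrate_steady_state <- function(individual, params = model_params()) {
  individual <- as.data.frame(individual, stringsAsFactors = FALSE)
  if (!is.finite(individual$tei_init) || individual$tei_init <= 0) {
    stop_domain("cannot calibrate individual '",
                individual$id %||% "?", "': non-positive baseline intake")
  }
  st <- baseline_body_state(individual, params)
  delta <- activity_coefficient(individual, params)
  k <- individual$tei_init - params$gamma_f * st$fat -
    params$gamma_l * st$lean - delta * individual$weight
  params$k_expenditure <- k
  expd <- k + params$gamma_f * st$fat + params$gamma_l * st$lean +
    delta * individual$weight
  attr(params, "residual") <- abs(individual$tei_init - expd)
  params
}

# shared derivative of the stacked cohort state; `lookup(t)` returns the
# list(net, carb) intake-change vectors at time t (days)
cohort_derivs <- function(t, y, env) {
  n <- env$n
  F <- y[seq_len(n)]
  L <- y[n + seq_len(n)]
  G <- y[2 * n + seq_len(n)]
  ECF <- y[3 * n + seq_len(n)]
  AT <- y[4 * n + seq_len(n)]
  p <- env$params
  d <- env$lookup(t)

  fshare <- p$forbes_c / (p$forbes_c + F)     # Forbes share going to lean
  if (p$fluid_compartments) {
    # carbohydrate intake and glycogen cannot go negative even when the
    # sugar cut exceeds the assumed baseline carbohydrate intake
    ci <- pmax(env$ci_b + d$carb, 0)
    dG <- (ci - env$k_g * pmax(G, 0)^2) / p$rho_g
    dECF <- (p$xi_ci * (ci - env$ci_b) / env$ci_b -
               p$xi_na * (ECF - env$ecf_b)) / p$na_conc
  } else {
    dG <- dECF <- numeric(n)
  }
  dAT <- (p$beta_at * d$net - AT) / p$tau_at

  bw <- F + L + G * (1 + p$hydration_ratio) + ECF
  omega <- env$k + p$gamma_f * F + p$gamma_l * L + env$delta * bw +
    p$beta_tef * d$net + AT
  s <- env$tei + d$net - p$rho_g * dG
  a <- p$eta_f * (1 - fshare) / p$rho_f + p$eta_l * fshare / p$rho_l
  tee <- (omega + a * s) / (1 + a)
  eb <- s - tee

  list(c((1 - fshare) * eb / p$rho_f,
         fshare * eb / p$rho_l,
         dG, dECF, dAT,
         env$tei + d$net - tee))              # cumulative energy imbalance
}

#' Simulate the cohort's body-weight response to a policy scenario
#'
#' Integrates the dynamic energy-balance model for every individual
#' simultaneously (one stacked state vector) with a fixed-step 4th-order
#' Runge-Kutta scheme at `params$step_days`-day steps, after per-individual
#' steady-state calibration. The intake forcing is the annual step
#' function implied by the scenario's [reduction_schedule()], held at the
#' final rollout level through the horizon.
#'
#' @param population individual-level `data.frame` (schema of
#'   [generate_population()]).
#' @param scenario an [policy_scenario()] object.
#' @param params [model_params()].
#' @param out_years years at which to record weight snapshots. Default
#'   every year up to the horizon.
#' @return `data.frame` with one row per individual: `id`, `weight0`,
#'   `weight_final`, `delta_weight`, `bmi0`, `bmi_final`, `delta_bmi`,
#'   `delta_sugar` (gross kcal/day at full rollout, <= 0) and
#'   `delta_intake` (net kcal/day at full rollout, <= 0). Attributes:
#'   `snapshot_years`, `snapshot_weight` (individuals x years matrix),
#'   `energy_integral` (kcal, cumulative intake minus expenditure, for
#'   conservation audits) and `state_baseline` / `state_final`
#'   (compartment masses).
#' @seealso [simulate_weight()] for a single individual with an explicit
#'   trajectory.
#' @export
#' @examples
#' pop <- generate_population(population_config(n_records = 50, seed = 1))
#' res <- simulate_cohort(pop, policy_scenario(horizon_years = 3, years = 2))
#' head(res)
simulate_cohort <- function(population, scenario = policy_scenario(),
                            params = model_params(), out_years = NULL) {
  check_population(population)
  n <- nrow(population)
  if (n == 0L) stop_domain("population is empty")
  schedule <- reduction_schedule(scenario$target, scenario$years,
                                 scenario$scenario)
  levels <- intake_levels(population$sugar_ssb, schedule, scenario, params)
  st <- baseline_body_state(population, params)
  delta <- activity_coefficient(population, params)
  k <- population$tei_init - params$gamma_f * st$fat -
    params$gamma_l * st$lean - delta * population$weight

  horizon <- scenario$horizon_years
  env <- list2env(list(
    n = n, params = params, tei = population$tei_init, k = k, delta = delta,
    ci_b = params$carb_share * population$tei_init,
    k_g = params$carb_share * population$tei_init / params$glycogen_init^2,
    ecf_b = st$ecf,
    lookup = function(t) {
      yr <- min(horizon, max(1L, ceiling(t / 365 - 1e-9)))
      list(net = levels$net[, yr], carb = levels$carb[, yr])
    }
  ), parent = emptyenv())

  out_years <- sort(unique(c(out_years %||% seq_len(horizon), horizon)))
  times <- c(0, 365 * out_years)
  y0 <- c(st$fat, st$lean, st$glycogen, st$ecf, rep(0, n), rep(0, n))
  sol <- deSolve::ode(y = y0, times = times, func = cohort_derivs,
                      parms = env, method = "rk4", hini = params$step_days)
  yT <- sol[nrow(sol), -1]
  if (any(!is.finite(yT))) {
    stop_domain("non-finite model state at the horizon; check intakes ",
                "and parameters")
  }
  pick <- function(slot, row) sol[row, 1 + (slot - 1) * n + seq_len(n)]
  wt_at <- function(row) {
    pick(1, row) + pick(2, row) +
      pick(3, row) * (1 + params$hydration_ratio) + pick(4, row)
  }
  snap <- vapply(seq_along(times), wt_at, numeric(n))
  if (n == 1L) snap <- matrix(snap, nrow = 1L)
  if (any(pick(1, nrow(sol)) < 0) || any(pick(2, nrow(sol)) < 0)) {
    stop_domain("negative compartment mass at the horizon")
  }
  w0 <- snap[, 1]
  wT <- snap[, ncol(snap)]
  res <- data.frame(
    id = population$id,
    weight0 = w0, weight_final = wT, delta_weight = wT - w0,
    bmi0 = w0 / population$height^2,
    bmi_final = wT / population$height^2,
    delta_bmi = (wT - w0) / population$height^2,
    delta_sugar = -population$sugar_ssb * schedule$cumulative[schedule$years],
    delta_intake = levels$net[, horizon],
    stringsAsFactors = FALSE
  )
  attr(res, "snapshot_years") <- c(0, out_years)
  attr(res, "snapshot_weight") <- snap
  attr(res, "energy_integral") <- pick(6, nrow(sol))
  attr(res, "state_baseline") <- st
  attr(res, "state_final") <- data.frame(
    fat = pick(1, nrow(sol)), lean = pick(2, nrow(sol)),
    glycogen = pick(3, nrow(sol)), ecf = pick(4, nrow(sol)),
    at = pick(5, nrow(sol)))
  attr(res, "scenario") <- scenario
  res
}

#' Simulate one individual's weight trajectory from an intake trajectory
#'
#' Integrates the same dynamic model as [simulate_cohort()] for a single
#' individual, driven by an explicit daily [build_trajectory()] object
#' (any piecewise-daily net/carbohydrate change is accepted), and returns
#' the full daily weight series.
#'
#' @param individual one-row `data.frame` (or list) with `sex`, `age`,
#'   `height`, `weight`, `tei_init`.
#' @param trajectory an [build_trajectory()] object (daily grid).
#' @param params [model_params()]; calibrated automatically if
#'   `k_expenditure` is `NA`.
#' @return object of class `ssb_weight_trajectory`: list with `days`,
#'   `weight` (kg series), `final_bmi` and `delta_weight`.
#' @export
#' @examples
#' ind <- data.frame(id = "ref", sex = "male", age = 35, height = 1.70,
#'                   weight = 70, tei_init = 2400, sugar_ssb = 100)
#' tr <- build_trajectory(ind, reduction_schedule(0.5, 10),
#'                        policy_scenario(horizon_years = 12))
#' sim <- simulate_weight(ind, tr, model_params())
#' sim$delta_weight
simulate_weight <- function(individual, trajectory, params = model_params()) {
  individual <- as.data.frame(individual, stringsAsFactors = FALSE)
  if (!inherits(trajectory, "ssb_trajectory")) {
    stop_domain("trajectory must be created by build_trajectory()")
  }
  if (is.na(params$k_expenditure)) {
    params <- calibrate_steady_state(individual, params)
  }
  st <- baseline_body_state(individual, params)
  nday <- max(trajectory$day)
  net <- trajectory$delta_intake
  carb <- trajectory$delta_carb
  env <- list2env(list(
    n = 1L, params = params, tei = individual$tei_init,
    k = params$k_expenditure,
    delta = activity_coefficient(individual, params),
    ci_b = params$carb_share * individual$tei_init,
    k_g = params$carb_share * individual$tei_init / params$glycogen_init^2,
    ecf_b = st$ecf,
    lookup = function(t) {
      i <- min(nday, max(1L, ceiling(t - 1e-9))) + 1L
      list(net = net[i], carb = carb[i])
    }
  ), parent = emptyenv())
  y0 <- c(st$fat, st$lean, st$glycogen, st$ecf, 0, 0)
  sol <- deSolve::ode(y = y0, times = 0:nday, func = cohort_derivs,
                      parms = env, method = "rk4", hini = params$step_days)
  weight <- sol[, 2] + sol[, 3] +
    sol[, 4] * (1 + params$hydration_ratio) + sol[, 5]
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    stop_domain("non-finite or non-positive weight during integration")
  }
  structure(list(days = sol[, 1], weight = weight,
                 final_bmi = weight[length(weight)] / individual$height^2,
                 delta_weight = weight[length(weight)] - weight[1]),
            class = "ssb_weight_trajectory")
}

#' @export
print.ssb_weight_trajectory <- function(x, ...) {
  cat(sprintf(paste0("Weight trajectory: %d days, start %.2f kg, ",
                     "end %.2f kg (delta %+.3f kg), final BMI %.2f\n"),
              length(x$days) - 1L, x$weight[1],
              x$weight[length(x$weight)], x$delta_weight, x$final_bmi))
  invisible(x)
}
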