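#' Policy scenario definition
#'
#' Bundles the reformulation target, the dietary compensation assumption
#' and the rollout shape into a single object consumed by the simulation
#' functions.
#'
#' @param target cumulative SSB sugar-reduction fraction at full rollout,
#'   in [0, 1]. Default 0.5.
#' @param compensation percent of the caloric reduction regained through
#'   other dietary sources, in [0, 100]. Default 43.
#' @param years rollout length (years). Default 10.
#' @param scenario rollout shape, see [reduction_schedule()]. Default
#'   `"decreasing"`.
#' @param horizon_years simulation length (years, `>= years`). Default 12:
#'   two extra years at the final sugar content let the lagged weight
#'   response settle and the rollout shapes converge.
#' @param goal added-sugar share of energy defining the policy goal.
#'   Default 0.10.
#' @return object of class `ssb_scenario`.
#' @export
#' @examples
#' policy_scenario()
#' policy_scenario(compensation = 0, scenario = "constant")
policy_scenario <- function(target = 0.5, compensation = 43, years = 10,
                            scenario = "decreasing", horizon_years = 12,
                            goal = 0.10) {
  if (compensation < 0 || compensation > 100) {
    stop_domain("compensation must lie in [0, 100]")
  }
  if (horizon_years < years) {
    stop_domain("horizon_years must be >= years")
  }
  structure(list(target = target, compensation = compensation,
                 years = years, scenario = scenario,
                 horizon_years = horizon_years, goal = goal),
            class = "ssb_scenario")
}

#' @export
print.ssb_scenario <- function(x, ...) {
  cat(sprintf(paste0("Policy scenario: %s rollout, target %.0f%%, ",
                     "compensation %.0f%%, %d-year rollout, %d-year horizon\n"),
              x$scenario, 100 * x$target, x$compensation, x$years,
              x$horizon_years))
  invisible(x)
}

#' Net daily caloric change from a cumulative sugar reduction
#'
#' The gross caloric cut is the individual's SSB added sugar times the
#' cumulative reduction fraction; a fraction `compensation/100` of that
#' cut is regained from other dietary sources, leaving the net change
#' `-sugar_ssb * cumulative_reduction * (1 - compensation / 100)`.
#'
#' @param sugar_ssb baseline added sugar from SSBs, kcal/day (>= 0).
#' @param cumulative_reduction cumulative reduction fraction, in [0, 1].
#' @param compensation percent compensated, in [0, 100].
#' @return kcal/day, `<= 0`.
#' @export
#' @examples
#' caloric_change(100, 0.5, 43)  # -28.5: a 50 kcal cut, 21.5 regained
caloric_change <- function(sugar_ssb, cumulative_reduction, compensation) {
  if (any(sugar_ssb < 0)) stop_domain("sugar_ssb must be non-negative")
  if (any(cumulative_reduction < 0 | cumulative_reduction > 1)) {
    stop_domain("cumulative_reduction must lie in [0, 1]")
  }
  if (any(compensation < 0 | compensation > 100)) {
    stop_domain("compensation must lie in [0, 100]")
  }
  -sugar_ssb * cumulative_reduction * (1 - compensation / 100)
}

#' Effective net reduction for a sensitivity cell
#'
#' Collapses a (target, compensation) pair of the sensitivity grid into
#' the single effective net reduction fraction
#' `target * (1 - compensation / 100)`.
#'
#' @param target reformulation target fraction, in [0, 1].
#' @param compensation percent compensated, in [0, 100].
#' @return effective net reduction fraction.
#' @export
#' @examples
#' overall_reduction(0.5, 43)  # 0.285
overall_reduction <- function(target, compensation) {
  if (any(compensation < 0 | compensation > 100)) {
    stop_domain("compensation must lie in [0, 100]")
  }
  target * (1 - compensation / 100)
}

#' Daily net intake-change trajectory for one individual
#'
#' Expands a schedule and scenario into the daily net caloric change an
#' individual experiences over the simulation horizon. The change is a
#' step function: the cumulative reduction for policy year `j` applies
#' from day `365 * (j - 1) + 1` through day `365 * j`, and the final-year
#' level is held through `horizon_years`. Day 0 is baseline (zero
#' change). A parallel carbohydrate-change column drives the
#' glycogen/fluid compartments of the weight model; under the default
#' `"net"` accounting it equals `carb_fraction` times the net change,
#' under `"gross"` it is the uncompensated sugar cut.
#'
#' @param individual one-row `data.frame` (or list) with at least
#'   `sugar_ssb`.
#' @param schedule an [reduction_schedule()] object consistent with
#'   `scenario` (same target and years).
#' @param scenario an [policy_scenario()] object.
#' @param params [model_params()]; supplies the carbohydrate accounting.
#' @return object of class `ssb_trajectory`: a `data.frame` with columns
#'   `day` (0 .. 365 * horizon), `delta_intake` (net kcal/day, <= 0) and
#'   `delta_carb` (kcal/day of carbohydrate change).
#' @export
#' @examples
#' ind <- list(sugar_ssb = 100)
#' tr <- build_trajectory(ind, reduction_schedule(0.5, 10), policy_scenario())
#' tr[c(1, 2, 366, 3651), ]
build_trajectory <- function(individual, schedule, scenario,
                             params = model_params()) {
  if (!inherits(schedule, "ssb_schedule")) {
    stop_domain("schedule must be created by reduction_schedule()")
  }
  if (!inherits(scenario, "ssb_scenario")) {
    stop_domain("scenario must be created by policy_scenario()")
  }
  if (scenario$horizon_years < schedule$years) {
    stop_domain("simulation horizon is shorter than the rollout")
  }
  if (abs(schedule$target - scenario$target) > 1e-12 ||
      schedule$years != scenario$years) {
    stop_domain("schedule and scenario disagree on target or years")
  }
  levels <- intake_levels(individual$sugar_ssb, schedule, scenario, params)
  day <- 0:(365 * scenario$horizon_years)
  yr <- pmin(ceiling(day / 365), scenario$horizon_years)
  delta_intake <- c(0, levels$net)[yr + 1]  # year 0 = baseline
  delta_carb <- c(0, levels$carb)[yr + 1]
  structure(data.frame(day = day, delta_intake = delta_intake,
                       delta_carb = delta_carb),
            class = c("ssb_trajectory", "data.frame"),
            sugar_ssb = individual$sugar_ssb)
}

# per-policy-year net and carbohydrate intake-change levels; rows =
# individuals, columns = years 1..horizon (vectorized over sugar_ssb)
intake_levels <- function(sugar_ssb, schedule, scenario, params) {
  horizon <- scenario$horizon_years
  cum <- c(schedule$cumulative,
           rep(schedule$cumulative[schedule$years],
               horizon - schedule$years))
  net <- outer(sugar_ssb, cum,
               function(s, r) caloric_change(s, r, scenario$compensation))
  carb <- if (params$carb_accounting == "net") {
    params$carb_fraction * net
  } else {
    outer(sugar_ssb, cum, function(s, r) -s * r)
  }
  list(net = net, carb = carb)
}
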