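#' Maximum SSB added sugar compatible with the added-sugar goal
#'
#' Solves, in closed form, the per-individual balance condition that the
#' added-sugar share of energy equal `goal` after the SSB sugar content is
#' changed and total energy moves by the same amount:
#' `goal = (ssb_max + others) / (tei_init + (ssb_max - ssb_init))`, giving
#' `ssb_max = (goal * (tei_init - ssb_init) - others) / (1 - goal)`.
#'
#' A negative result signals that added sugar from non-SSB sources alone
#' already exceeds the goal, in which case the policy removes all SSB
#' sugar (see [delta_change()]).
#'
#' @param tei_init baseline total energy intake, kcal/day (> 0).
#' @param ssb_init baseline added sugar from SSBs, kcal/day (>= 0).
#' @param others baseline added sugar from non-SSB sources, kcal/day (>= 0).
#' @param goal target added-sugar share of total energy, in (0, 1).
#'   Default 0.10.
#' @return kcal/day of SSB added sugar at the goal; may be negative.
#' @export
#' @examples
#' max_ssb_sugar(2000, 150, 150)   # 38.89 kcal/day
#' max_ssb_sugar(2000, 100, 300)   # negative: full removal regime
max_ssb_sugar <- function(tei_init, ssb_init, others, goal = 0.10) {
  if (any(goal <= 0 | goal >= 1)) stop_domain("goal must lie in (0, 1)")
  if (any(tei_init <= 0)) stop_domain("tei_init must be positive")
  if (any(ssb_init < 0) || any(others < 0)) {
    stop_domain("sugar intakes must be non-negative")
  }
  (goal * (tei_init - ssb_init) - others) / (1 - goal)
}

#' Individual change in SSB added sugar under the goal
#'
#' Returns the signed change (<= 0, a reduction) in SSB added sugar:
#' zero when baseline SSB sugar is already at or below [max_ssb_sugar()];
#' a reduction to exactly the maximum when above it; and full removal of
#' SSB sugar when non-SSB added sugar alone exceeds the goal (negative
#' maximum).
#'
#' @inheritParams max_ssb_sugar
#' @return kcal/day, `<= 0`.
#' @export
#' @examples
#' delta_change(2000, 150, 150)   # -111.11
#' delta_change(2000, 0, 0)       # 0: nothing to reduce
#' delta_change(2000, 100, 300)   # -100: full removal
delta_change <- function(tei_init, ssb_init, others, goal = 0.10) {
  smax <- max_ssb_sugar(tei_init, ssb_init, others, goal)
  ifelse(smax < 0, -ssb_init,
         ifelse(ssb_init > smax, smax - ssb_init, 0))
}

#' Per-individual reformulation target results
#'
#' Tabulates, for every record of a population, the maximum SSB sugar at
#' the goal, the implied sugar change and the reduction proportion
#' `prop = |delta_change| / sugar_ssb` (defined as 0 for non-consumers,
#' the continuous extension of a zero change).
#'
#' @param population individual-level `data.frame` with columns
#'   `tei_init`, `sugar_ssb`, `sugar_other` (and `id`).
#' @param goal target added-sugar share of energy. Default 0.10.
#' @return `data.frame` with columns `id`, `ssb_max`, `delta_change`,
#'   `prop`.
#' @export
target_results <- function(population, goal = 0.10) {
  check_population(population, c("id", "tei_init", "sugar_ssb", "sugar_other"))
  smax <- max_ssb_sugar(population$tei_init, population$sugar_ssb,
                        population$sugar_other, goal)
  dc <- delta_change(population$tei_init, population$sugar_ssb,
                     population$sugar_other, goal)
  prop <- ifelse(population$sugar_ssb > 0, -dc / population$sugar_ssb, 0)
  data.frame(id = population$id, ssb_max = smax, delta_change = dc,
             prop = prop, stringsAsFactors = FALSE)
}

#' Survey-weighted average required reduction proportion
#'
#' The policy target is the survey-weighted mean of the individual
#' reduction proportions, `sum(w_i * prop_i) / sum(w_i)`. The denominator
#' can cover the whole population (default; non-consumers contribute
#' `prop = 0`) or SSB consumers only.
#'
#' @inheritParams target_results
#' @param denominator `"population"` (default) or `"consumers"`.
#' @return fraction in `[0, 1]`.
#' @export
#' @examples
#' pop <- generate_population(population_config(n_records = 500, seed = 1))
#' required_proportion(pop)
required_proportion <- function(population, goal = 0.10,
                                denominator = c("population", "consumers")) {
  denominator <- match.arg(denominator)
  check_population(population, c("id", "tei_init", "sugar_ssb",
                                 "sugar_other", "survey_weight"))
  if (nrow(population) == 0L) stop_domain("population is empty")
  tr <- target_results(population, goal)
  w <- population$survey_weight
  if (denominator == "consumers") {
    keep <- population$sugar_ssb > 0
    if (!any(keep)) stop_domain("no SSB consumers in the population")
    return(wtd_mean(tr$prop[keep], w[keep]))
  }
  wtd_mean(tr$prop, w)
}

#' Round a raw target fraction to a policy step
#'
#' Policy targets are stated on a coarse grid (e.g. multiples of 5%); the
#' default mode rounds down, so a raw requirement of 52.2% becomes 50%.
#'
#' @param raw fraction in `[0, 1]`.
#' @param step grid step (> 0). Default 0.05.
#' @param mode `"down"` (default), `"nearest"` or `"up"`.
#' @return fraction on the step grid.
#' @export
#' @examples
#' round_target(0.522)          # 0.50
#' round_target(0.999)          # 0.95
round_target <- function(raw, step = 0.05, mode = c("down", "nearest", "up")) {
  mode <- match.arg(mode)
  if (step <= 0) stop_domain("step must be positive")
  if (any(raw < 0 | raw > 1)) stop_domain("raw must lie in [0, 1]")
  k <- switch(mode,
              down = floor(raw / step + 1e-9),
              nearest = round(raw / step),
              up = ceiling(raw / step - 1e-9))
  k * step
}
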