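#' First-year reduction of the decreasing rollout
#'
#' With equal multiplicative year-over-year steps, reaching a cumulative
#' reduction `target` after `years` years requires a first-year reduction
#' `1 - (1 - target)^(1/years)`: each year the remaining sugar content is
#' multiplied by the same factor.
#'
#' @param target cumulative reduction fraction at full rollout, in (0, 1).
#' @param years rollout length in years (>= 1).
#' @return fraction reduced in year 1.
#' @export
#' @examples
#' first_year_reduction(0.5, 10)  # 0.067: 6.7%
first_year_reduction <- function(target, years) {
  if (any(target <= 0 | target >= 1)) stop_domain("target must lie in (0, 1)")
  if (any(years < 1)) stop_domain("years must be >= 1")
  1 - (1 - target)^(1 / years)
}

#' Cumulative sugar-reduction schedule for a rollout scenario
#'
#' Builds the cumulative yearly reduction fractions for the three rollout
#' shapes:
#' \describe{
#'   \item{decreasing}{constant multiplicative step: cumulative reduction
#'     `1 - (1 - r1)^j` in year `j`, with `r1` from
#'     [first_year_reduction()]. Yearly increments shrink over time.}
#'   \item{constant}{linear: `target * j / years` (5 percentage points of
#'     the baseline content per year for a 50% target over 10 years).}
#'   \item{increasing}{the decreasing scenario's yearly increments applied
#'     in reverse order, so the rollout starts gently and ends with the
#'     largest step; both endpoints coincide with the other scenarios.}
#' }
#'
#' The degenerate targets 0 and 1 are accepted for sensitivity grids and
#' yield all-zero and all-one schedules.
#'
#' @param target cumulative reduction fraction at full rollout, in [0, 1].
#' @param years rollout length in years (>= 1).
#' @param scenario `"decreasing"` (default), `"constant"` or
#'   `"increasing"`.
#' @return object of class `ssb_schedule`: a list with `scenario`,
#'   `target`, `years`, `cumulative` (length `years`) and `increments`.
#' @seealso [schedule_decreasing()], [schedule_constant()],
#'   [schedule_increasing()]
#' @export
#' @examples
#' s <- reduction_schedule(0.5, 10)
#' round(100 * s$cumulative, 1)
reduction_schedule <- function(target, years,
                               scenario = c("decreasing", "constant",
                                            "increasing")) {
  scenario <- match.arg(scenario)
  if (any(target < 0 | target > 1)) stop_domain("target must lie in [0, 1]")
  if (years < 1 || years != round(years)) {
    stop_domain("years must be a whole number >= 1")
  }
  j <- seq_len(years)
  if (target == 0 || target == 1) {
    cum <- rep(target, years)
  } else {
    cum <- switch(scenario,
      decreasing = 1 - (1 - first_year_reduction(target, years))^j,
      constant = target * j / years,
      increasing = {
        dec <- 1 - (1 - first_year_reduction(target, years))^j
        cumsum(rev(diff(c(0, dec))))
      })
  }
  structure(list(scenario = scenario, target = target, years = years,
                 cumulative = cum, increments = diff(c(0, cum))),
            class = "ssb_schedule")
}

#' @rdname reduction_schedule
#' @export
schedule_decreasing <- function(target, years) {
  reduction_schedule(target, years, "decreasing")
}

#' @rdname reduction_schedule
#' @export
schedule_constant <- function(target, years) {
  reduction_schedule(target, years, "constant")
}

#' @rdname reduction_schedule
#' @export
schedule_increasing <- function(target, years) {
  reduction_schedule(target, years, "increasing")
}

#' @export
print.ssb_schedule <- function(x, ...) {
  cat(sprintf("Sugar-reduction schedule: %s, target %.1f%% over %d years\n",
              x$scenario, 100 * x$target, x$years))
  print(round(setNames(100 * x$cumulative, paste0("y", seq_len(x$years))), 1))
  invisible(x)
}

#' @export
as.data.frame.ssb_schedule <- function(x, ...) {
  data.frame(year = seq_len(x$years),
             cumulative_fraction = x$cumulative,
             increment = x$increments)
}
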