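`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)

#' Survey-weighted mean
#'
#' Convenience wrapper returning `sum(w * x) / sum(w)` with `NA` handling
#' disabled: missing values are an error in this package's data model.
#'
#' @param x numeric vector.
#' @param w positive weights, same length as `x`.
#' @return scalar weighted mean.
#' @keywords internal
wtd_mean <- function(x, w) {
  if (length(x) != length(w)) stop_domain("x and w must have equal length")
  sw <- sum(w)
  if (sw <= 0) stop_domain("weights must have a positive sum")
  sum(w * x) / sw
}

#' Age group used for stratified reporting
#'
#' Collapses continuous age into the three reporting groups: young adults
#' (20-39), adults (40-59) and older adults (60+).
#'
#' @param age numeric vector of ages in years (>= 20).
#' @return factor with levels `"20-39"`, `"40-59"`, `"60+"`.
#' @export
#' @examples
#' age_group(c(20, 39.9, 40, 59.9, 60, 85))
age_group <- function(age) {
  if (any(age < 20, na.rm = TRUE)) stop_domain("age_group() is defined for adults (age >= 20)")
  cut(age, breaks = c(20, 40, 60, Inf), right = FALSE,
      labels = c("20-39", "40-59", "60+"))
}

# check that a data frame carries the individual-level columns we need
check_population <- function(population, cols = individual_columns()) {
  missing <- setdiff(cols, names(population))
  if (length(missing) > 0L) {
    stop_domain("population is missing required columns: ",
                paste(missing, collapse = ", "))
  }
  invisible(population)
}

individual_columns <- function() {
  c("id", "sex", "age", "height", "weight", "ses", "tei_init",
    "sugar_total", "sugar_ssb", "sugar_other", "survey_weight",
    "stratum", "psu")
}
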