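#' Classify BMI into reporting categories
#'
#' Categories follow the survey analysis convention: underweight is
#' collapsed into `normal` (BMI < 25), `overweight` is 25 <= BMI < 30 and
#' `obese` is BMI >= 30 (half-open boundaries).
#'
#' @param bmi kg/m^2 (> 0), vectorized.
#' @return factor with levels `normal`, `overweight`, `obese`.
#' @export
#' @examples
#' classify_bmi(c(17, 24.999, 25, 29.9, 30))
classify_bmi <- function(bmi) {
  if (any(!is.finite(bmi) | bmi <= 0)) stop_domain("bmi must be positive")
  cut(bmi, breaks = c(0, 25, 30, Inf), right = FALSE,
      labels = c("normal", "overweight", "obese"))
}

#' Project a prevalence change to a count of individuals
#'
#' @param delta_pp change in prevalence, percentage points (signed).
#' @param projected_adults adult population the prevalence applies to
#'   (> 0).
#' @return signed number of individuals.
#' @export
#' @examples
#' project_cases(-3.9, 90e6)
project_cases <- function(delta_pp, projected_adults) {
  if (any(projected_adults <= 0)) {
    stop_domain("projected_adults must be positive")
  }
  delta_pp / 100 * projected_adults
}

bmi_categories <- c("normal", "overweight", "obese")

# named vector of all point estimates for one subset, given weights
outcome_estimates <- function(sub, w) {
  pb <- vapply(bmi_categories,
               function(cc) wtd_mean(sub$cat0 == cc, w), numeric(1))
  pf <- vapply(bmi_categories,
               function(cc) wtd_mean(sub$catT == cc, w), numeric(1))
  c(mean_delta_sugar = wtd_mean(sub$delta_sugar, w),
    mean_delta_intake = wtd_mean(sub$delta_intake, w),
    mean_delta_weight = wtd_mean(sub$delta_weight, w),
    mean_delta_bmi = wtd_mean(sub$delta_bmi, w),
    setNames(pb, paste0("prev_base_", bmi_categories)),
    setNames(pf, paste0("prev_final_", bmi_categories)),
    setNames(100 * (pf - pb), paste0("delta_pp_", bmi_categories)))
}

# Rao-Wu-Yue rescaling bootstrap multipliers: within each design stratum
# with n_h PSUs, draw n_h - 1 with replacement; each record inherits its
# PSU's multiplier count * n_h / (n_h - 1). Single-PSU strata get 1.
bootstrap_multipliers <- function(stratum, psu, n_boot) {
  n <- length(stratum)
  M <- matrix(1, n, n_boot)
  for (h in unique(stratum)) {
    rows <- which(stratum == h)
    psus <- unique(psu[rows])
    nh <- length(psus)
    if (nh < 2L) next
    pidx <- match(psu[rows], psus)
    for (b in seq_len(n_boot)) {
      counts <- tabulate(sample.int(nh, nh - 1L, replace = TRUE), nbins = nh)
      M[rows, b] <- counts[pidx] * nh / (nh - 1L)
    }
  }
  M
}

# Taylor-linearization variance of a survey-weighted mean (with-replacement
# PSU approximation): var = sum_h n_h/(n_h-1) sum_c (z_hc - zbar_h)^2 with
# z_i = w_i (x_i - xbar_w) / sum(w)
linearized_se <- function(x, w, stratum, psu) {
  xbar <- wtd_mean(x, w)
  z <- w * (x - xbar) / sum(w)
  key <- paste(stratum, psu)
  zt <- tapply(z, key, sum)
  hs <- vapply(strsplit(names(zt), " ", fixed = TRUE), `[`, character(1), 1)
  v <- 0
  for (h in unique(hs)) {
    zh <- zt[hs == h]
    nh <- length(zh)
    if (nh < 2L) next
    v <- v + nh / (nh - 1L) * sum((zh - mean(zh))^2)
  }
  sqrt(v)
}

#' Survey-weighted outcome summary with design-based confidence intervals
#'
#' Aggregates per-individual simulation results to survey-weighted mean
#' changes (added sugar, energy intake, weight, BMI) and BMI-category
#' prevalences at baseline and at the horizon, overall and stratified by
#' sex, age group and SES. Absolute changes in prevalence are expressed in
#' percentage points (pp), relative changes as a percent of the baseline
#' prevalence, and case counts are projected onto an external adult
#' population (each stratum receives its share of the survey weight
#' mass).
#'
#' Confidence intervals account for the stratified clustered design
#' through either a Rao-Wu-Yue rescaling bootstrap over PSUs (default) or
#' Taylor linearization. Under linearization the intervals for relative
#' changes and case counts are scaled from the percentage-point interval
#' (baseline prevalence treated as fixed); the bootstrap propagates all
#' quantities through every replicate.
#'
#' @param population individual-level `data.frame` (schema of
#'   [generate_population()]).
#' @param results per-individual results from [simulate_cohort()].
#' @param strata character vector among `"overall"`, `"sex"`,
#'   `"age_group"`, `"ses"`.
#' @param consumers_only restrict to SSB consumers (`sugar_ssb > 0`)
#'   before aggregating. Default `FALSE`.
#' @param ci_method `"bootstrap"` (default) or `"linearization"`.
#' @param n_boot bootstrap replicates. Default 500.
#' @param conf confidence level. Default 0.95.
#' @param projected_adults adult population for case projections.
#'   Default 90e6 (documented example value; projections are an external
#'   input, never fetched).
#' @param boot_seed optional integer seed for the bootstrap replicates.
#' @return object of class `ssb_outcomes`: list with `means` (one row per
#'   stratum), `prevalence` (one row per stratum x BMI category) and
#'   `settings`. Interval columns carry `_lo`/`_hi` suffixes.
#' @export
#' @examples
#' pop <- generate_population(population_config(n_records = 120, seed = 2))
#' res <- simulate_cohort(pop, policy_scenario(years = 2, horizon_years = 3))
#' out <- weighted_summary(pop, res, strata = "overall", n_boot = 50,
#'                         boot_seed = 1)
#' out$prevalence
weighted_summary <- function(population, results,
                             strata = c("overall", "sex", "age_group", "ses"),
                             consumers_only = FALSE,
                             ci_method = c("bootstrap", "linearization"),
                             n_boot = 500, conf = 0.95,
                             projected_adults = 9e7, boot_seed = NULL) {
  ci_method <- match.arg(ci_method)
  strata <- match.arg(strata, several.ok = TRUE)
  check_population(population)
  df <- merge(population, results, by = "id", sort = FALSE)
  if (nrow(df) != nrow(population)) {
    stop_domain("population and results do not match one-to-one on id")
  }
  if (consumers_only) df <- df[df$sugar_ssb > 0, , drop = FALSE]
  if (nrow(df) == 0L) stop_domain("no records to summarize")
  df$cat0 <- as.character(classify_bmi(df$bmi0))
  df$catT <- as.character(classify_bmi(df$bmi_final))
  df$age_group <- as.character(age_group(df$age))
  df$overall <- "overall"
  total_w <- sum(df$survey_weight)

  M <- NULL
  if (ci_method == "bootstrap") {
    if (!is.null(boot_seed)) set.seed(boot_seed)
    M <- bootstrap_multipliers(df$stratum, df$psu, n_boot)
    zq <- qnorm(1 - (1 - conf) / 2)
  } else {
    # survey convention: t quantile at the design degrees of freedom
    design_df <- length(unique(paste(df$stratum, df$psu))) -
      length(unique(df$stratum))
    zq <- stats::qt(1 - (1 - conf) / 2, max(design_df, 1))
  }

  means <- list(); prev <- list()
  for (sv in strata) {
    levs <- unique(df[[sv]])
    for (lv in levs) {
      rows <- which(df[[sv]] == lv)
      if (length(rows) == 0L) {
        warning("empty stratum ", sv, "=", lv, " omitted")
        next
      }
      sub <- df[rows, , drop = FALSE]
      w <- sub$survey_weight
      est <- outcome_estimates(sub, w)
      share <- sum(w) / total_w

      if (ci_method == "bootstrap") {
        reps <- vapply(seq_len(ncol(M)), function(b) {
          outcome_estimates(sub, w * M[rows, b])
        }, numeric(length(est)))
        se <- apply(reps, 1, sd)
      } else {
        vars <- list(mean_delta_sugar = sub$delta_sugar,
                     mean_delta_intake = sub$delta_intake,
                     mean_delta_weight = sub$delta_weight,
                     mean_delta_bmi = sub$delta_bmi)
        for (cc in bmi_categories) {
          vars[[paste0("prev_base_", cc)]] <- as.numeric(sub$cat0 == cc)
          vars[[paste0("prev_final_", cc)]] <- as.numeric(sub$catT == cc)
          vars[[paste0("delta_pp_", cc)]] <-
            100 * (as.numeric(sub$catT == cc) - as.numeric(sub$cat0 == cc))
        }
        se <- vapply(names(est), function(nm) {
          linearized_se(vars[[nm]], w, sub$stratum, sub$psu)
        }, numeric(1))
      }
      lo <- est - zq * se
      hi <- est + zq * se

      mcols <- c("mean_delta_sugar", "mean_delta_intake",
                 "mean_delta_weight", "mean_delta_bmi")
      mrow <- data.frame(stratum_var = sv, stratum = as.character(lv),
                         n = length(rows), pop_share = share,
                         stringsAsFactors = FALSE)
      for (nm in mcols) {
        mrow[[nm]] <- est[[nm]]
        mrow[[paste0(nm, "_lo")]] <- lo[[nm]]
        mrow[[paste0(nm, "_hi")]] <- hi[[nm]]
      }
      means[[paste(sv, lv)]] <- mrow

      adults <- projected_adults * share
      for (cc in bmi_categories) {
        pb <- est[[paste0("prev_base_", cc)]]
        dnm <- paste0("delta_pp_", cc)
        prow <- data.frame(
          stratum_var = sv, stratum = as.character(lv), category = cc,
          prev_baseline = pb,
          prev_baseline_lo = lo[[paste0("prev_base_", cc)]],
          prev_baseline_hi = hi[[paste0("prev_base_", cc)]],
          prev_final = est[[paste0("prev_final_", cc)]],
          prev_final_lo = lo[[paste0("prev_final_", cc)]],
          prev_final_hi = hi[[paste0("prev_final_", cc)]],
          delta_pp = est[[dnm]], delta_pp_lo = lo[[dnm]],
          delta_pp_hi = hi[[dnm]],
          stringsAsFactors = FALSE
        )
        # relative change uses the baseline prevalence (in percent) as
        # denominator; cases scale pp onto the stratum's projected adults
        prow$delta_relative <- prow$delta_pp / pb
        prow$delta_relative_lo <- prow$delta_pp_lo / pb
        prow$delta_relative_hi <- prow$delta_pp_hi / pb
        prow$cases_millions <- project_cases(prow$delta_pp, adults) / 1e6
        prow$cases_millions_lo <- project_cases(prow$delta_pp_lo, adults) / 1e6
        prow$cases_millions_hi <- project_cases(prow$delta_pp_hi, adults) / 1e6
        prev[[paste(sv, lv, cc)]] <- prow
      }
    }
  }
  structure(list(means = do.call(rbind, c(means, make.row.names = FALSE)),
                 prevalence = do.call(rbind, c(prev, make.row.names = FALSE)),
                 settings = list(ci_method = ci_method, n_boot = n_boot,
                                 conf = conf,
                                 projected_adults = projected_adults,
                                 consumers_only = consumers_only)),
            class = "ssb_outcomes")
}

#' @export
print.ssb_outcomes <- function(x, digits = 2, ...) {
  cat("Survey-weighted policy outcomes",
      if (x$settings$consumers_only) "(SSB consumers only)" else "", "\n")
  ov <- x$means[x$means$stratum_var == "overall", , drop = FALSE]
  if (nrow(ov) == 1) {
    cat(sprintf("  mean change: sugar %.1f kcal/d, intake %.1f kcal/d, weight %.2f kg, BMI %.2f kg/m2\n",
                ov$mean_delta_sugar, ov$mean_delta_intake,
                ov$mean_delta_weight, ov$mean_delta_bmi))
    pv <- x$prevalence[x$prevalence$stratum_var == "overall", , drop = FALSE]
    for (i in seq_len(nrow(pv))) {
      cat(sprintf("  %-10s baseline %.1f%%  change %+.1f pp (%+.1f%% of baseline, %+.2f M cases)\n",
                  pv$category[i], 100 * pv$prev_baseline[i], pv$delta_pp[i],
                  pv$delta_relative[i], pv$cases_millions[i]))
    }
  }
  cat("  strata:", paste(unique(x$means$stratum_var), collapse = ", "),
      "| CI:", x$settings$ci_method, "\n")
  invisible(x)
}

#' Sensitivity grid of mean weight change over targets and compensations
#'
#' Runs the full simulation pipeline once per (target, compensation) cell
#' and tabulates the survey-weighted mean weight change at the horizon.
#' Rows index compensation (percent), columns the reformulation target
#' (fraction). The full-compensation row is identically zero and more
#' reduction / less compensation never yields less weight loss.
#'
#' @param population individual-level `data.frame`.
#' @param targets reduction targets, fractions in [0, 1].
#' @param compensations compensation percents in [0, 100].
#' @param scenario rollout shape. Default `"decreasing"`.
#' @param years,horizon_years rollout and simulation lengths. Defaults 10
#'   and 12.
#' @param params [model_params()].
#' @return numeric matrix (compensations x targets) of mean weight change
#'   in kg, with dimnames.
#' @export
#' @examples
#' pop <- generate_population(population_config(n_records = 40, seed = 5))
#' sensitivity_matrix(pop, targets = c(0, 0.5), compensations = c(0, 100),
#'                    years = 2, horizon_years = 2)
sensitivity_matrix <- function(population, targets = seq(0, 1, 0.25),
                               compensations = seq(0, 100, 25),
                               scenario = "decreasing",
                               years = 10, horizon_years = 12,
                               params = model_params()) {
  if (any(targets < 0 | targets > 1)) stop_domain("targets must lie in [0, 1]")
  if (any(compensations < 0 | compensations > 100)) {
    stop_domain("compensations must lie in [0, 100]")
  }
  out <- matrix(NA_real_, length(compensations), length(targets),
                dimnames = list(compensation = paste0(compensations, "%"),
                                target = paste0(100 * targets, "%")))
  for (i in seq_along(compensations)) {
    for (j in seq_along(targets)) {
      sc <- policy_scenario(target = targets[j],
                            compensation = compensations[i],
                            years = years, scenario = scenario,
                            horizon_years = horizon_years)
      res <- simulate_cohort(population, sc, params,
                             out_years = horizon_years)
      out[i, j] <- wtd_mean(res$delta_weight, population$survey_weight)
    }
  }
  out
}
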