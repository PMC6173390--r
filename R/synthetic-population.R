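#' Configuration for the synthetic survey population generator
#'
#' Builds the full parameterization used by [generate_population()]. The
#' defaults emulate the adult analytic sample of a national dietary survey
#' (Mexico, 2012): ~3,005 records expanding to ~64.9 million adults, mean
#' added-sugar intake 244.9 kcal/day (12.6% of total energy intake), mean
#' SSB added sugar 101.1 kcal/day, 51.8% of adults consuming SSBs in the
#' past 24 h, and baseline BMI-category prevalences near 30.4 / 38.7 /
#' 30.9% (normal incl. underweight / overweight / obese), with sex,
#' age-group and socioeconomic gradients in intake.
#'
#' Cell-level intake targets (sex x age group x SES) are composed
#' multiplicatively from the configured marginal means, each factor's
#' ratios normalized so its population-weighted average is 1; the
#' configured overall means are therefore reproduced in expectation.
#' Within a cell, energy intake is log-normal, the added-sugar share of
#' energy is log-normal (capped at `max_sugar_share`), and SSB sugar is a
#' Beta-distributed fraction of total added sugar for the consumer
#' subpopulation, with a point mass at zero for non-consumers.
#'
#' @param n_records number of sampled individuals. Default 3005.
#' @param target_expansion sum of survey weights (population represented).
#'   Default 64,885,715.
#' @param seed integer seed; generation is fully deterministic given the
#'   config.
#' @param consumer_share fraction of individuals with any SSB added sugar
#'   (24-h recall zero inflation). Default 0.518.
#' @param mean_sugar_total,mean_sugar_ssb overall mean added-sugar intake
#'   from all sources and from SSBs (kcal/day). Defaults 244.9 and 101.1.
#' @param pct_tei_sugar overall added-sugar share of total energy intake,
#'   used to set the mean energy intake. Default 0.126.
#' @param sex_props,age_props,ses_props marginal category proportions
#'   (male/female; 20-39/40-59/60+; low/middle/high SES).
#' @param sex_sugar,age_sugar,ses_sugar marginal mean total added sugar
#'   (kcal/day) per category, same order as the proportion vectors.
#' @param sex_ssb,age_ssb,ses_ssb marginal mean SSB added sugar (kcal/day).
#' @param sex_pct,age_pct,ses_pct marginal added-sugar %TEI (fractions),
#'   used to derive marginal mean energy intake.
#' @param bmi_probs_male,bmi_probs_female baseline BMI-category
#'   probabilities (normal, overweight, obese) per sex; a log-normal BMI
#'   distribution is solved to match them exactly in expectation.
#' @param sdlog_tei,sdlog_share log-scale dispersions of energy intake and
#'   of the added-sugar share. Defaults 0.30 and 0.50.
#' @param beta_nu concentration of the Beta distribution of the SSB
#'   fraction of added sugar among consumers. Default 5.
#' @param max_sugar_share,max_ssb_fraction caps keeping the intake
#'   invariants `sugar_ssb <= sugar_total <= tei_init` strict. Defaults
#'   0.60 and 0.95.
#' @param rank_corr Gaussian-copula correlation between energy intake and
#'   BMI. Default 0.1 (diet-BMI correlations in recall data are weak).
#' @param n_strata,psus_per_stratum survey design layout. Defaults 30 and 3.
#' @param icc between-PSU intraclass correlation of log energy intake.
#'   Default 0.02.
#' @param weight_cv coefficient of variation of the survey weights.
#'   Default 0.3.
#'
#' @return object of class `ssb_population_config`; element `cells` holds
#'   the realized per-cell targets (after caps), which are the reference
#'   values for calibration checks.
#' @export
#' @examples
#' cfg <- population_config(n_records = 500, seed = 42)
#' head(cfg$cells)
population_config <- function(n_records = 3005,
                              target_expansion = 64885715,
                              seed = 1,
                              consumer_share = 0.518,
                              mean_sugar_total = 244.9,
                              mean_sugar_ssb = 101.1,
                              pct_tei_sugar = 0.126,
                              sex_props = c(male = 0.477, female = 0.523),
                              age_props = c(`20-39` = 0.446, `40-59` = 0.368, `60+` = 0.186),
                              ses_props = c(low = 0.297, middle = 0.301, high = 0.402),
                              sex_sugar = c(278.9, 213.9),
                              age_sugar = c(285.7, 235.7, 165.2),
                              ses_sugar = c(213.1, 255.0, 260.7),
                              sex_ssb = c(128.0, 76.7),
                              age_ssb = c(130.8, 90.3, 51.4),
                              ses_ssb = c(84.5, 118.0, 100.8),
                              sex_pct = c(0.129, 0.122),
                              age_pct = c(0.138, 0.122, 0.103),
                              ses_pct = c(0.113, 0.127, 0.134),
                              bmi_probs_male = c(0.364, 0.395, 0.241),
                              bmi_probs_female = c(0.250, 0.380, 0.370),
                              sdlog_tei = 0.30, sdlog_share = 0.50,
                              beta_nu = 5,
                              max_sugar_share = 0.60, max_ssb_fraction = 0.95,
                              rank_corr = 0.1,
                              n_strata = 30, psus_per_stratum = 3,
                              icc = 0.02, weight_cv = 0.3) {
  if (n_records < 1) stop_domain("n_records must be >= 1")
  if (target_expansion <= 0) stop_domain("target_expansion must be positive")
  if (consumer_share < 0 || consumer_share > 1) {
    stop_domain("consumer_share must lie in [0, 1]")
  }
  means <- c(mean_sugar_total, mean_sugar_ssb, sex_sugar, age_sugar,
             ses_sugar, sex_ssb, age_ssb, ses_ssb)
  if (any(means <= 0)) stop_domain("all configured intake means must be positive")
  if (icc < 0 || icc >= 1) stop_domain("icc must lie in [0, 1)")
  if (abs(rank_corr) >= 1) stop_domain("rank_corr must lie in (-1, 1)")
  for (p in list(sex_props, age_props, ses_props)) {
    if (abs(sum(p) - 1) > 0.02 || any(p <= 0)) {
      stop_domain("category proportions must be positive and sum to ~1")
    }
  }

  mean_tei <- mean_sugar_total / pct_tei_sugar
  sex_tei <- sex_sugar / sex_pct
  age_tei <- age_sugar / age_pct
  ses_tei <- ses_sugar / ses_pct

  # normalize each factor's ratios so the weighted average is exactly 1;
  # cell mean = overall * r_sex * r_age * r_ses then matches the overall
  # mean in expectation under independent factor draws
  norm_ratio <- function(m, overall, p) {
    r <- m / overall
    r / sum(p / sum(p) * r)
  }
  grid <- expand.grid(sex = names(sex_props), age_group = names(age_props),
                      ses = names(ses_props), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  ridx <- cbind(match(grid$sex, names(sex_props)),
                match(grid$age_group, names(age_props)),
                match(grid$ses, names(ses_props)))
  cell_of <- function(sexm, agem, sesm, overall) {
    overall *
      norm_ratio(sexm, overall, sex_props)[ridx[, 1]] *
      norm_ratio(agem, overall, age_props)[ridx[, 2]] *
      norm_ratio(sesm, overall, ses_props)[ridx[, 3]]
  }
  cells <- grid
  cells$mean_tei <- cell_of(sex_tei, age_tei, ses_tei, mean_tei)
  cells$mean_sugar <- cell_of(sex_sugar, age_sugar, ses_sugar, mean_sugar_total)
  raw_ssb <- cell_of(sex_ssb, age_ssb, ses_ssb, mean_sugar_ssb)
  # consumer-mean SSB fraction of added sugar, capped to keep ssb < total;
  # store the realized (post-cap) target so calibration is checked against
  # what the generator actually aims for
  mu_frac <- if (consumer_share > 0) {
    pmin(max_ssb_fraction, raw_ssb / (consumer_share * cells$mean_sugar))
  } else {
    rep(0, nrow(cells))
  }
  cells$ssb_fraction <- mu_frac
  cells$mean_ssb <- mu_frac * consumer_share * cells$mean_sugar
  cells$share_tei <- cells$mean_sugar / cells$mean_tei

  solve_bmi <- function(probs) {
    if (abs(sum(probs) - 1) > 1e-6 || any(probs <= 0)) {
      stop_domain("BMI category probabilities must be positive and sum to 1")
    }
    sigma <- (log(30) - log(25)) / (qnorm(probs[1] + probs[2]) - qnorm(probs[1]))
    mu <- log(25) - sigma * qnorm(probs[1])
    c(meanlog = mu, sdlog = sigma)
  }

  structure(list(
    n_records = n_records, target_expansion = target_expansion, seed = seed,
    consumer_share = consumer_share,
    mean_sugar_total = mean_sugar_total, mean_sugar_ssb = mean_sugar_ssb,
    mean_tei = mean_tei,
    sex_props = sex_props, age_props = age_props, ses_props = ses_props,
    cells = cells,
    bmi_lnorm = rbind(male = solve_bmi(bmi_probs_male),
                      female = solve_bmi(bmi_probs_female)),
    height_mean = c(male = 1.64, female = 1.51),
    height_sd = c(male = 0.07, female = 0.065),
    sdlog_tei = sdlog_tei, sdlog_share = sdlog_share, beta_nu = beta_nu,
    max_sugar_share = max_sugar_share, max_ssb_fraction = max_ssb_fraction,
    rank_corr = rank_corr,
    n_strata = n_strata, psus_per_stratum = psus_per_stratum,
    icc = icc, weight_cv = weight_cv
  ), class = "ssb_population_config")
}

#' Generate a seeded synthetic survey population
#'
#' Draws `config$n_records` adults with the joint structure described in
#' [population_config()]: categorical strata with configured proportions,
#' log-normal intakes with multiplicative cell targets and a mild
#' between-PSU intraclass correlation, zero-inflated SSB sugar, a
#' log-normal BMI per sex coupled to intake through a Gaussian copula, and
#' log-normal survey weights rescaled to the target expansion.
#'
#' @param config an [population_config()] object.
#' @return a `data.frame` with one row per individual and columns
#'   `id, sex, age, height, weight, ses, tei_init, sugar_total, sugar_ssb,
#'   sugar_other, survey_weight, stratum, psu`. Deterministic given
#'   `config` (including its seed).
#' @export
#' @examples
#' pop <- generate_population(population_config(n_records = 200, seed = 7))
#' summary(pop$sugar_total)
generate_population <- function(config) {
  if (!inherits(config, "ssb_population_config")) {
    stop_domain("config must be created by population_config()")
  }
  set.seed(config$seed)
  n <- config$n_records

  sex <- sample(names(config$sex_props), n, replace = TRUE,
                prob = config$sex_props)
  ageg <- sample(names(config$age_props), n, replace = TRUE,
                 prob = config$age_props)
  ses <- sample(names(config$ses_props), n, replace = TRUE,
                prob = config$ses_props)
  age <- ifelse(ageg == "20-39", runif(n, 20, 40),
         ifelse(ageg == "40-59", runif(n, 40, 60),
                60 + pmin(rexp(n, rate = 1 / 8), 29)))

  stratum <- sample.int(config$n_strata, n, replace = TRUE)
  psu_in_str <- sample.int(config$psus_per_stratum, n, replace = TRUE)
  psu <- (stratum - 1L) * config$psus_per_stratum + psu_in_str
  u_psu <- rnorm(config$n_strata * config$psus_per_stratum)

  cells <- config$cells
  ci <- match(paste(sex, ageg, ses),
              paste(cells$sex, cells$age_group, cells$ses))

  # energy intake: log-normal around the cell mean, PSU-level share of the
  # log variance equal to the configured ICC
  z_i <- rnorm(n)
  z <- sqrt(config$icc) * u_psu[psu] + sqrt(1 - config$icc) * z_i
  s1 <- config$sdlog_tei
  tei <- cells$mean_tei[ci] * exp(s1 * z - s1^2 / 2)

  # added-sugar share of energy, capped; sugar and energy are positively
  # coupled through the shared cell structure
  s2 <- config$sdlog_share
  share <- pmin(config$max_sugar_share,
                cells$share_tei[ci] * exp(s2 * rnorm(n) - s2^2 / 2))
  sugar_total <- share * tei

  consumer <- runif(n) < config$consumer_share
  mu <- cells$ssb_fraction[ci]
  frac <- rep(0, n)
  if (any(consumer)) {
    nu <- config$beta_nu
    frac[consumer] <- rbeta(sum(consumer), mu[consumer] * nu,
                            (1 - mu[consumer]) * nu)
  }
  frac <- pmin(frac, config$max_ssb_fraction)
  sugar_ssb <- ifelse(consumer, frac * sugar_total, 0)
  sugar_other <- sugar_total - sugar_ssb

  # BMI: per-sex log-normal matching the configured category prevalences,
  # rank-correlated with the individual intake innovation
  z_b <- config$rank_corr * z_i + sqrt(1 - config$rank_corr^2) * rnorm(n)
  bl <- config$bmi_lnorm[sex, , drop = FALSE]
  bmi <- exp(bl[, "meanlog"] + bl[, "sdlog"] * z_b)
  height <- pmin(pmax(rnorm(n, config$height_mean[sex],
                            config$height_sd[sex]), 1.30), 2.10)
  weight <- bmi * height^2

  w0 <- exp(rnorm(n, 0, sqrt(log(1 + config$weight_cv^2))))
  survey_weight <- w0 * config$target_expansion / sum(w0)

  data.frame(
    id = sprintf("P%05d", seq_len(n)),
    sex = sex, age = age, height = height, weight = weight, ses = ses,
    tei_init = tei, sugar_total = sugar_total, sugar_ssb = sugar_ssb,
    sugar_other = sugar_other, survey_weight = survey_weight,
    stratum = stratum, psu = psu,
    stringsAsFactors = FALSE
  )
}

#' Apply the analytic-sample exclusion filters
#'
#' Reproduces the exclusion rules of the emulated survey analysis:
#' implausible energy reporters with `|ln(TEI / TER)|` more than
#' `sd_limit` sample standard deviations from the sample mean (TER = total
#' energy requirement, see `ter_model`), extreme SSB consumption above
#' `ssb_limit` kcal/day, participants younger than 20, and records with
#' missing or non-positive weight or height.
#'
#' The log-ratio rule is centered on the sample mean, so it is invariant
#' to any multiplicative rescaling of the TER model: only the *relative*
#' energy requirement matters. With zero dispersion (all log-ratios equal)
#' no record is excluded by that rule. All rules are evaluated on the
#' input sample, so per-rule counts refer to the same denominator.
#'
#' @param population individual-level `data.frame` (see
#'   [generate_population()] for the schema).
#' @param ter_model `"expenditure"` (default): TER is the body-weight
#'   model's baseline expenditure at default activity,
#'   `k_base + gamma_f * F + gamma_l * L` with `F` from
#'   [baseline_fat_mass()]; or `"mifflin"`: Mifflin-St Jeor resting
#'   metabolic rate times the physical activity level `params$pal`.
#' @param params [model_params()] supplying the expenditure constants.
#' @param ssb_limit exclusion threshold for SSB caloric intake (kcal/day).
#'   Default 3000.
#' @param sd_limit number of standard deviations for the log energy-ratio
#'   rule. Default 3.
#' @return a list with elements `population` (kept rows) and `log`, a
#'   `data.frame` with one row per rule: `rule`, `n_excluded`, `ids`
#'   (semicolon-separated).
#' @export
#' @examples
#' pop <- generate_population(population_config(n_records = 300, seed = 3))
#' excl <- apply_exclusions(pop)
#' excl$log
apply_exclusions <- function(population,
                             ter_model = c("expenditure", "mifflin"),
                             params = model_params(),
                             ssb_limit = 3000, sd_limit = 3) {
  ter_model <- match.arg(ter_model)
  check_population(population)

  bad_anthro <- !is.finite(population$weight) | population$weight <= 0 |
    !is.finite(population$height) | population$height <= 0
  too_young <- !bad_anthro & population$age < 20
  ssb_extreme <- population$sugar_ssb > ssb_limit

  ter <- rep(NA_real_, nrow(population))
  ok <- !bad_anthro
  ter[ok] <- total_energy_requirement(population[ok, , drop = FALSE],
                                      ter_model, params)
  lr <- log(population$tei_init / ter)
  s <- sd(lr, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    energy_extreme <- rep(FALSE, nrow(population))
  } else {
    m <- mean(lr, na.rm = TRUE)
    energy_extreme <- !is.na(lr) & abs(lr - m) > sd_limit * s
  }

  rules <- list(energy_ratio = energy_extreme, ssb_extreme = ssb_extreme,
                under_20 = too_young, missing_anthropometry = bad_anthro)
  drop <- Reduce(`|`, rules)
  log <- data.frame(
    rule = names(rules),
    n_excluded = vapply(rules, sum, integer(1)),
    ids = vapply(rules, function(r) paste(population$id[r], collapse = ";"),
                 character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(population = population[!drop, , drop = FALSE], log = log)
}

# total energy requirement used by the implausible-reporter filter
total_energy_requirement <- function(population, ter_model, params) {
  if (ter_model == "expenditure") {
    # clamped fat predictions are fine here: the rule below only uses
    # relative requirements and is robust to individual clamps
    fat <- suppressWarnings(
      baseline_fat_mass(population$sex, population$age,
                        population$height, population$weight,
                        bounds = params$fat_bounds))
    lean <- population$weight - fat -
      params$glycogen_init * (1 + params$hydration_ratio) -
      params$ecf_fraction * population$weight
    delta <- activity_coefficient(population, params)
    params$k_base + params$gamma_f * fat + params$gamma_l * lean +
      delta * population$weight
  } else {
    params$pal * mifflin_rmr(population$sex, population$age,
                             population$height, population$weight)
  }
}
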