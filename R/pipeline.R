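#' Configuration of an end-to-end pipeline run
#'
#' @param population_config an [population_config()] object, or `NULL`
#'   when reading from `population_csv`.
#' @param population_csv path to an individual-level CSV with the schema
#'   of [generate_population()]; validated with
#'   [validate_population_csv()]. Exactly one population source must be
#'   given.
#' @param scenario an [policy_scenario()] object.
#' @param params [model_params()].
#' @param strata reporting strata, see [weighted_summary()].
#' @param ci_method,n_boot CI settings, see [weighted_summary()].
#' @param projected_adults adult population for case projections.
#' @param ter_model exclusion-filter energy-requirement model, see
#'   [apply_exclusions()].
#' @param output_dir directory for the run artifacts; created if needed.
#' @param seed master seed; population generation and the bootstrap use
#'   derived sub-seeds so changing `n_boot` never perturbs the population.
#' @return object of class `ssb_run_config`.
#' @export
run_config <- function(population_config = NULL, population_csv = NULL,
                       scenario = policy_scenario(),
                       params = model_params(),
                       strata = c("overall", "sex", "age_group", "ses"),
                       ci_method = "bootstrap", n_boot = 500,
                       projected_adults = 9e7,
                       ter_model = "expenditure",
                       output_dir = tempfile("ssbreform-run-"),
                       seed = 1L) {
  if (is.null(population_config) == is.null(population_csv)) {
    stop_domain("give exactly one population source: ",
                "population_config or population_csv")
  }
  if (!is.null(population_config)) {
    population_config$seed <- seed %% 2147483647L
  }
  structure(list(population_config = population_config,
                 population_csv = population_csv,
                 scenario = scenario, params = params, strata = strata,
                 ci_method = ci_method, n_boot = n_boot,
                 projected_adults = projected_adults,
                 ter_model = ter_model,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "ssb_run_config")
}

#' Run the full reformulation pipeline
#'
#' Orchestrates every stage: population (synthetic or CSV), exclusion
#' filters, reformulation-target report, reduction schedule, cohort
#' weight simulation, and survey-weighted outcome tables. All artifacts
#' are written as CSV under `config$output_dir` together with a manifest
#' (config hash, seed, versions); identical config and seed give
#' byte-identical outputs.
#'
#' Files written: `population.csv`, `exclusions.csv`, `target_report.csv`,
#' `schedule.csv`, `individual_results.csv`, `outcomes_means.csv`,
#' `outcomes_prevalence.csv`, `manifest.txt`.
#'
#' @param config an [run_config()] object.
#' @return (invisibly) a list with all in-memory stage outputs:
#'   `population`, `exclusion_log`, `targets`, `required_prop`,
#'   `rounded_target`, `schedule`, `results`, `outcomes`, `files`.
#' @export
#' @examples
#' cfg <- run_config(population_config(n_records = 60, seed = 3),
#'                   scenario = policy_scenario(years = 2, horizon_years = 2),
#'                   n_boot = 20, seed = 3)
#' run <- run_pipeline(cfg)
#' run$outcomes$means$mean_delta_weight[1]
run_pipeline <- function(config) {
  if (!inherits(config, "ssb_run_config")) {
    stop_domain("config must be created by run_config()")
  }
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop_domain("pipeline stage '", what, "' failed: ", conditionMessage(e))
    })
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)

  pop <- stage("population", {
    if (!is.null(config$population_config)) {
      generate_population(config$population_config)
    } else {
      rep_ <- validate_population_csv(config$population_csv)
      if (!rep_$valid) {
        stop("population CSV failed validation: ",
             paste(utils::head(rep_$errors$problem, 3), collapse = "; "))
      }
      read.csv(config$population_csv, stringsAsFactors = FALSE)
    }
  })
  excl <- stage("exclusions",
                apply_exclusions(pop, ter_model = config$ter_model,
                                 params = config$params))
  kept <- excl$population

  targets <- stage("target", target_results(kept, config$scenario$goal))
  req <- stage("target", required_proportion(kept, config$scenario$goal))
  rounded <- round_target(req)

  schedule <- stage("schedule",
                    reduction_schedule(config$scenario$target,
                                       config$scenario$years,
                                       config$scenario$scenario))
  results <- stage("weight model",
                   simulate_cohort(kept, config$scenario, config$params))
  outcomes <- stage("outcomes",
                    weighted_summary(kept, results, strata = config$strata,
                                     ci_method = config$ci_method,
                                     n_boot = config$n_boot,
                                     projected_adults = config$projected_adults,
                                     boot_seed = (config$seed + 1L) %% 2147483647L))

  files <- c(population = out("population.csv"),
             exclusions = out("exclusions.csv"),
             target_report = out("target_report.csv"),
             schedule = out("schedule.csv"),
             individual_results = out("individual_results.csv"),
             outcomes_means = out("outcomes_means.csv"),
             outcomes_prevalence = out("outcomes_prevalence.csv"),
             manifest = out("manifest.txt"))
  wcsv <- function(x, f) write.csv(x, f, row.names = FALSE)
  wcsv(pop, files["population"])
  wcsv(excl$log, files["exclusions"])
  tr <- targets
  tr$required_prop <- req
  tr$rounded_target <- rounded
  wcsv(tr, files["target_report"])
  wcsv(as.data.frame(schedule), files["schedule"])
  wcsv(results, files["individual_results"])
  wcsv(outcomes$means, files["outcomes_means"])
  wcsv(outcomes$prevalence, files["outcomes_prevalence"])

  cfg_dump <- tempfile()
  dput(config[setdiff(names(config), "output_dir")], file = cfg_dump)
  manifest <- c(
    sprintf("config_hash: %s", unname(tools::md5sum(cfg_dump))),
    sprintf("seed: %d", config$seed),
    sprintf("package: ssbreform %s", as.character(packageVersion("ssbreform"))),
    sprintf("r_version: %s", R.version.string),
    sprintf("n_population: %d", nrow(pop)),
    sprintf("n_kept: %d", nrow(kept)),
    sprintf("required_proportion: %.6f", req),
    sprintf("rounded_target: %.2f", rounded),
    sprintf("scenario: %s target=%g compensation=%g years=%d horizon=%d",
            config$scenario$scenario, config$scenario$target,
            config$scenario$compensation, config$scenario$years,
            config$scenario$horizon_years)
  )
  writeLines(manifest, files["manifest"])
  unlink(cfg_dump)

  invisible(list(population = pop, exclusion_log = excl$log,
                 targets = targets, required_prop = req,
                 rounded_target = rounded, schedule = schedule,
                 results = results, outcomes = outcomes, files = files))
}

#' Validate an individual-level population CSV
#'
#' Schema, invariant and unit checks for externally supplied population
#' tables: required columns, positive weights and anthropometry, adult
#' ages, intake ordering `0 <= sugar_ssb <= sugar_total <= tei_init`,
#' exact `sugar_other = sugar_total - sugar_ssb`, and a height unit
#' heuristic (median height above 3 suggests centimeters instead of
#' meters).
#'
#' @param path readable CSV file.
#' @return list with `valid` (logical) and `errors`, a `data.frame` with
#'   columns `row` (NA for file-level problems), `column`, `problem`.
#' @export
validate_population_csv <- function(path) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  errors <- list()
  flag <- function(row, column, problem) {
    errors[[length(errors) + 1L]] <<-
      data.frame(row = row, column = column, problem = problem,
                 stringsAsFactors = FALSE)
  }
  missing <- setdiff(individual_columns(), names(df))
  if (length(missing) > 0L) {
    flag(NA_integer_, paste(missing, collapse = ","), "missing column")
  } else {
    if (stats::median(df$height, na.rm = TRUE) > 3) {
      flag(NA_integer_, "height",
           "implausible unit: values look like centimeters, expected meters")
    }
    rowflag <- function(bad, column, problem) {
      for (r in which(bad)) flag(r, column, problem)
    }
    rowflag(!is.finite(df$survey_weight) | df$survey_weight <= 0,
            "survey_weight", "must be positive")
    rowflag(is.finite(df$height) & (df$height <= 0 | df$height > 2.5),
            "height", "outside plausible range (m)")
    rowflag(!is.finite(df$weight) | df$weight <= 0 | df$weight > 400,
            "weight", "outside plausible range (kg)")
    rowflag(df$age < 20, "age", "below adult range")
    rowflag(df$sugar_ssb < 0 | df$sugar_total < 0 | df$tei_init <= 0,
            "intakes", "negative intake")
    rowflag(df$sugar_ssb > df$sugar_total, "sugar_ssb",
            "exceeds sugar_total")
    rowflag(df$sugar_total > df$tei_init, "sugar_total",
            "exceeds total energy intake")
    rowflag(abs(df$sugar_other - (df$sugar_total - df$sugar_ssb)) > 1e-6,
            "sugar_other", "not equal to sugar_total - sugar_ssb")
    rowflag(!df$sex %in% c("male", "female"), "sex",
            "must be 'male' or 'female'")
  }
  errors <- if (length(errors) > 0L) {
    do.call(rbind, c(errors, make.row.names = FALSE))
  } else {
    data.frame(row = integer(), column = character(), problem = character(),
               stringsAsFactors = FALSE)
  }
  list(valid = nrow(errors) == 0L, errors = errors)
}
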