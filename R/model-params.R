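#' Parameters of the dynamic energy-balance body-weight model
#'
#' Returns the parameter set of the adult Chow-Hall dynamic weight-change
#' model used by [simulate_weight()] and [simulate_cohort()]. Defaults are
#' the canonical published values of that model family; every constant can
#' be overridden, none is hard-coded elsewhere.
#'
#' The model tracks fat mass F, lean tissue L, glycogen G (with bound
#' water), extracellular fluid (ECF) and an adaptive-thermogenesis offset
#' AT. Energy imbalances are partitioned between fat and lean via the
#' Forbes share `p = C / (C + F)`.
#'
#' @param rho_f,rho_l,rho_g energy densities of fat, lean tissue and
#'   glycogen (kcal/kg). Defaults 9440, 1816, 4180.
#' @param gamma_f,gamma_l tissue-specific resting expenditure coefficients
#'   (kcal/kg/day). Defaults 3.2 and 22.
#' @param eta_f,eta_l biochemical synthesis/turnover costs of fat and lean
#'   tissue deposition (kcal/kg). Defaults 180 and 230.
#' @param beta_tef thermic effect of food: fraction of an intake *change*
#'   spent digesting it. Default 0.10.
#' @param beta_at,tau_at adaptive thermogenesis magnitude (fraction of the
#'   intake change) and first-order time constant (days). Defaults 0.14
#'   and 14.
#' @param forbes_k Forbes lean/fat partition constant (kg). The effective
#'   constant used in the share `p = C/(C+F)` is
#'   `C = forbes_k * rho_l / rho_f`. Default 10.4.
#' @param hydration_ratio grams of water stored per gram of glycogen.
#'   Default 3.7.
#' @param glycogen_init baseline glycogen mass (kg). Default 0.5.
#' @param carb_share baseline carbohydrate share of total energy intake,
#'   used to size the glycogen/fluid response. Default 0.5.
#' @param ecf_fraction baseline extracellular fluid as a fraction of body
#'   weight. Only fluid *changes* affect predicted weight change. Default
#'   0.20.
#' @param xi_na,xi_ci,na_conc extracellular-fluid response coefficients:
#'   sodium excretion feedback (mg/L/day), carbohydrate coupling (mg/day)
#'   and extracellular sodium concentration (mg/L). Defaults 3000, 4000,
#'   3220. Dietary sodium itself is held constant by a sugar
#'   reformulation, so it enters only through these feedback terms.
#' @param fluid_compartments logical; include the glycogen and
#'   extracellular-fluid sub-model (default `TRUE`). With `FALSE` only the
#'   fat/lean core is simulated, which is convenient for isolating the
#'   validated two-compartment dynamics in tests.
#' @param carb_accounting `"net"` (default) or `"gross"`: whether the
#'   carbohydrate change forcing glycogen and fluid follows the net
#'   (compensated) energy change or the gross sugar cut. See the package
#'   vignette for why `"net"` reproduces the full-compensation null.
#' @param carb_fraction fraction of the net intake change treated as
#'   carbohydrate under `"net"` accounting. Default 1 (the change removed
#'   is added sugar).
#' @param fat_bounds admissible baseline body-fat range as fractions of
#'   body weight; regression predictions outside it are clamped with a
#'   warning. Default `c(0.05, 0.60)`.
#' @param delta_activity physical-activity expenditure coefficient
#'   (kcal/kg/day), multiplying current body weight in total expenditure.
#'   `NULL` (default) derives it per individual from the physical
#'   activity level as `((1 - beta_tef) * pal - 1) * RMR / weight` with a
#'   Mifflin-St Jeor resting metabolic rate, the convention of the adult
#'   model family; a number fixes it for everyone.
#' @param k_base population-default residual expenditure constant
#'   (kcal/day) used when expenditure must be predicted *without*
#'   individual calibration (the `"expenditure"` TER model of
#'   [apply_exclusions()]). Default 1200.
#' @param pal physical activity level multiplier for the `"mifflin"` TER
#'   model. Default 1.55 (low-active adult).
#' @param step_days integration step of the fixed-step 4th-order scheme
#'   (days). Default 1.
#' @param k_expenditure individual residual expenditure constant
#'   (kcal/day); `NA` until set by [calibrate_steady_state()].
#'
#' @return an object of class `ssb_model_params` (a validated named list).
#' @seealso [calibrate_steady_state()], [simulate_cohort()]
#' @export
#' @examples
#' p <- model_params()
#' p$gamma_l
#' model_params(beta_tef = 0)$beta_tef
model_params <- function(rho_f = 9440, rho_l = 1816, rho_g = 4180,
                         gamma_f = 3.2, gamma_l = 22,
                         eta_f = 180, eta_l = 230,
                         beta_tef = 0.10, beta_at = 0.14, tau_at = 14,
                         forbes_k = 10.4, hydration_ratio = 3.7,
                         glycogen_init = 0.5, carb_share = 0.5,
                         ecf_fraction = 0.20,
                         xi_na = 3000, xi_ci = 4000, na_conc = 3220,
                         fluid_compartments = TRUE,
                         carb_accounting = c("net", "gross"),
                         carb_fraction = 1,
                         fat_bounds = c(0.05, 0.60),
                         delta_activity = NULL,
                         k_base = 1200, pal = 1.55,
                         step_days = 1, k_expenditure = NA_real_) {
  carb_accounting <- match.arg(carb_accounting)
  p <- list(rho_f = rho_f, rho_l = rho_l, rho_g = rho_g,
            gamma_f = gamma_f, gamma_l = gamma_l,
            eta_f = eta_f, eta_l = eta_l,
            beta_tef = beta_tef, beta_at = beta_at, tau_at = tau_at,
            forbes_k = forbes_k, hydration_ratio = hydration_ratio,
            glycogen_init = glycogen_init, carb_share = carb_share,
            ecf_fraction = ecf_fraction,
            xi_na = xi_na, xi_ci = xi_ci, na_conc = na_conc,
            fluid_compartments = isTRUE(fluid_compartments),
            carb_accounting = carb_accounting,
            carb_fraction = carb_fraction,
            fat_bounds = fat_bounds,
            delta_activity = delta_activity,
            k_base = k_base, pal = pal,
            step_days = step_days, k_expenditure = k_expenditure)
  positive <- c("rho_f", "rho_l", "rho_g", "tau_at", "forbes_k",
                "hydration_ratio", "na_conc", "step_days")
  for (nm in positive) {
    if (!is.numeric(p[[nm]]) || p[[nm]] <= 0) {
      stop_domain("model parameter '", nm, "' must be a positive number")
    }
  }
  if (!(carb_share > 0 && carb_share <= 1)) {
    stop_domain("carb_share must be in (0, 1]")
  }
  if (length(fat_bounds) != 2 || fat_bounds[1] <= 0 || fat_bounds[2] >= 1 ||
      fat_bounds[1] >= fat_bounds[2]) {
    stop_domain("fat_bounds must be increasing fractions inside (0, 1)")
  }
  # Forbes share constant scaled by the density ratio
  p$forbes_c <- p$forbes_k * p$rho_l / p$rho_f
  structure(p, class = "ssb_model_params")
}

#' @export
print.ssb_model_params <- function(x, ...) {
  cat("Dynamic body-weight model parameters (Chow-Hall family)\n")
  cat(sprintf("  energy densities (kcal/kg): fat %g, lean %g, glycogen %g\n",
              x$rho_f, x$rho_l, x$rho_g))
  cat(sprintf("  expenditure slopes (kcal/kg/day): fat %g, lean %g\n",
              x$gamma_f, x$gamma_l))
  cat(sprintf("  TEF %g, AT %g (tau %g d), Forbes C %.3f kg\n",
              x$beta_tef, x$beta_at, x$tau_at, x$forbes_c))
  cat(sprintf("  fluid sub-model: %s (carb accounting: %s)\n",
              if (x$fluid_compartments) "on" else "off", x$carb_accounting))
  cat(sprintf("  calibration k: %s kcal/day\n",
              if (is.na(x$k_expenditure)) "uncalibrated" else
                format(x$k_expenditure)))
  invisible(x)
}
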