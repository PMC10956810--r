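# Canonical parameter names the engine requires.  Cost means are USD/month
# (2023 USD, 34 THB/USD recorded as metadata only), probabilities are per
# one-month cycle, utilities on the 0-1 scale.
.required_parameters <- c(
  "hr_pfs", "hr_os",
  "p_progress_bsc_early", "p_progress_bsc_late",
  "p_death_bsc_early", "p_death_bsc_late",
  "cost_bsc_month", "cost_drug_month", "cost_admin_month",
  "cost_lab_inr", "cost_lab_afp", "cost_lab_lft", "cost_lab_cbc",
  "cost_ct_scan", "cost_chest_scan",
  "cost_travel_month", "cost_food_month", "cost_caregiver_month",
  "u_progression_free", "u_progression"
)

#' Base-case parameter table
#'
#' The full published parameter set: hazard ratios for progression-free
#' and overall survival of atezolizumab+bevacizumab (A+B) versus best
#' supportive care (BSC), the piecewise-constant BSC monthly transition
#' probabilities, every monthly cost item, and the two state utilities.
#'
#' @return A tibble with columns `name`, `mean`, `se`, `family`, `role`.
#' @export
default_parameters <- function() {
  validate_parameters(tibble::tribble(
    ~name,                   ~mean, ~se,   ~family,     ~role,
    "hr_pfs",                0.34,  0.06,  "lognormal", "hazard_ratio",
    "hr_os",                 0.40,  0.07,  "lognormal", "hazard_ratio",
    "p_progress_bsc_early",  0.29,  NA,    "fixed",     "transition_prob",
    "p_progress_bsc_late",   0.24,  NA,    "fixed",     "transition_prob",
    "p_death_bsc_early",     0.17,  NA,    "fixed",     "transition_prob",
    "p_death_bsc_late",      0.10,  NA,    "fixed",     "transition_prob",
    "cost_bsc_month",        489,   49,    "gamma",     "cost",
    "cost_drug_month",       6135,  614,   "gamma",     "cost",
    "cost_admin_month",      21,    2,     "gamma",     "cost",
    "cost_lab_inr",          3,     2.2,   "gamma",     "cost",
    "cost_lab_afp",          12,    7.4,   "gamma",     "cost",
    "cost_lab_lft",          15,    8.6,   "gamma",     "cost",
    "cost_lab_cbc",          4,     2.7,   "gamma",     "cost",
    "cost_ct_scan",          218,   11.1,  "gamma",     "cost",
    "cost_chest_scan",       76,    3.9,   "gamma",     "cost",
    "cost_travel_month",     5,     0.4,   "gamma",     "cost",
    "cost_food_month",       2,     0.2,   "gamma",     "cost",
    "cost_caregiver_month",  3,     1.2,   "gamma",     "cost",
    "u_progression_free",    0.89,  0.02,  "beta",      "utility",
    "u_progression",         0.58,  0.08,  "beta",      "utility"
  ))
}

.default_settings <- function() {
  list(
    cycle_length_months = 1,
    start_age = 50,
    horizon_cycles = 600,
    discount_rate_annual = 0.03,
    discounting = "annual_step",
    half_cycle_correction = FALSE,
    lognormal_parametrization = "moments",
    wtp_thresholds = c(4678, 60819),
    psa_iterations = 5000,
    psa_seed = 1234,
    ae_cost_oneoff = 0,
    progression_switch_cycle = 7,
    death_switch_cycle = 13,
    monitoring = list(labs = 1, ct = 2, chest = 3)
  )
}

.default_budget <- function() {
  list(
    incidence_per_year = 27394,
    hcc_share = 0.50,
    bclc_c_share = 0.112,
    initial_access = 0.146,
    access_increment = 0.065,
    years = 5,
    patients_per_year = c(224, 324, 425, 525, 625)
  )
}

#' Assemble a model configuration
#'
#' A configuration bundles the parameter table with the model settings
#' (cycle length, cohort starting age, horizon, discounting rule,
#' willingness-to-pay thresholds, monitoring frequencies, PSA controls)
#' and the budget-impact constants (national incidence, HCC and BCLC-C
#' shares, access-rate ramp, printed per-year patient counts).
#'
#' @param parameters Parameter table (default [default_parameters()]).
#' @param settings,budget Named lists overriding individual defaults; any
#'   field not supplied keeps its base-case value.
#' @return A validated object of class `hcc_config`.
#' @examples
#' cfg <- default_config()
#' cfg$settings$wtp_thresholds
#' # a 20% drug price cut:
#' cheap <- default_config()
#' cheap$parameters$mean[cheap$parameters$name == "cost_drug_month"] <- 4908
#' @export
default_config <- function(parameters = default_parameters(),
                           settings = list(), budget = list()) {
  cfg <- structure(
    list(
      parameters = validate_parameters(parameters),
      settings = modifyList(.default_settings(), settings),
      budget = modifyList(.default_budget(), budget)
    ),
    class = "hcc_config"
  )
  validate_config(cfg)
}

#' @export
print.hcc_config <- function(x, ...) {
  s <- x$settings
  cat("<hcc_config>\n")
  cat(sprintf("  %d parameters (%d uncertain), cycle %g month(s), start age %g\n",
              nrow(x$parameters), sum(x$parameters$family != "fixed"),
              s$cycle_length_months, s$start_age))
  cat(sprintf("  horizon %d cycles, discount %.1f%%/yr (%s), PSA %d iters (seed %d)\n",
              s$horizon_cycles, 100 * s$discount_rate_annual, s$discounting,
              s$psa_iterations, s$psa_seed))
  cat(sprintf("  WTP thresholds: %s USD/QALY\n",
              paste(format(s$wtp_thresholds, big.mark = ","), collapse = ", ")))
  invisible(x)
}

#' Validate a model configuration
#'
#' Checks structural completeness (every canonical parameter present) and
#' all numeric invariants (non-negative discount rate, horizon of at least
#' one cycle, monitoring frequencies of at least one cycle, strictly
#' positive willingness-to-pay thresholds, access rates within `[0, 1]`).
#'
#' @param config An `hcc_config`.
#' @return The config, invisibly unchanged, or an error naming the
#'   offending field.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "hcc_config")) abort("not an `hcc_config` object.")
  config$parameters <- validate_parameters(config$parameters)
  missing <- setdiff(.required_parameters, config$parameters$name)
  if (length(missing)) {
    abort(paste0("configuration lacks mandatory parameter(s): ",
                 paste(missing, collapse = ", ")))
  }
  s <- config$settings
  if (s$discount_rate_annual < 0) abort("`discount_rate_annual` must be >= 0.")
  if (s$horizon_cycles < 1) abort("`horizon_cycles` must be >= 1.")
  if (any(unlist(s$monitoring) < 1)) {
    abort("monitoring frequencies must be >= 1 cycle.")
  }
  if (any(s$wtp_thresholds <= 0)) {
    abort("`wtp_thresholds` must be strictly positive.")
  }
  if (!s$discounting %in% c("annual_step", "per_cycle")) {
    abort("`discounting` must be \"annual_step\" or \"per_cycle\".")
  }
  if (!s$lognormal_parametrization %in% c("moments", "naive")) {
    abort("`lognormal_parametrization` must be \"moments\" or \"naive\".")
  }
  if (s$ae_cost_oneoff < 0) abort("`ae_cost_oneoff` must be >= 0.")
  if (s$psa_iterations < 1) abort("`psa_iterations` must be >= 1.")
  if (s$progression_switch_cycle < 2 || s$death_switch_cycle < 2) {
    abort("piecewise switch cycles must be >= 2.")
  }
  b <- config$budget
  shares <- c(b$hcc_share, b$bclc_c_share, b$initial_access)
  if (any(shares < 0 | shares > 1)) {
    abort("budget shares and access rates must lie in [0, 1].")
  }
  rates <- b$initial_access + b$access_increment * (seq_len(b$years) - 1)
  if (any(rates < 0 | rates > 1)) {
    abort("access-rate ramp leaves [0, 1] within the projection window.")
  }
  if (!is.null(b$patients_per_year) &&
      length(b$patients_per_year) != b$years) {
    abort("`patients_per_year` override must have one entry per year.")
  }
  invisible(config)
}

#' Load a model configuration from a YAML file
#'
#' The schema mirrors [default_config()]: a top-level `parameters` list of
#' `{name, mean, se, family, role}` records (mandatory, must include every
#' canonical parameter) and optional `settings` and `budget_impact` maps
#' whose omitted keys fall back to the base-case defaults.  The bundled
#' fixture encodes the full published parameter set:
#' `system.file("extdata", "imbrave_th_2023.yaml", package = "hccmarkov")`.
#'
#' @param path Path to a YAML configuration.
#' @return A validated `hcc_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$parameters)) {
    abort("config file has no `parameters` block.")
  }
  params <- purrr::map_dfr(raw$parameters, function(p) {
    for (field in c("name", "mean", "family", "role")) {
      if (is.null(p[[field]])) {
        abort(paste0("parameter entry missing field `", field, "`",
                     if (!is.null(p$name)) paste0(" (", p$name, ")")))
      }
    }
    tibble::tibble(
      name = p$name, mean = as.numeric(p$mean),
      se = if (is.null(p$se)) NA_real_ else as.numeric(p$se),
      family = p$family, role = p$role
    )
  })
  settings <- raw$settings %||% list()
  if (!is.null(settings$wtp_thresholds)) {
    settings$wtp_thresholds <- as.numeric(unlist(settings$wtp_thresholds))
  }
  budget <- raw$budget_impact %||% list()
  if (!is.null(budget$patients_per_year)) {
    budget$patients_per_year <- as.numeric(unlist(budget$patients_per_year))
  }
  default_config(parameters = params, settings = settings, budget = budget)
}

#' Write a configuration to YAML
#'
#' @param config An `hcc_config`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  config <- validate_config(config)
  params <- purrr::pmap(config$parameters, function(name, mean, se, family, role) {
    p <- list(name = name, mean = mean, family = family, role = role)
    if (!is.na(se)) p$se <- se
    p
  })
  yaml::write_yaml(
    list(parameters = params, settings = config$settings,
         budget_impact = config$budget),
    path
  )
  invisible(path)
}
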