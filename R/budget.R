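#' Annual eligible uHCC population
#'
#' Funnels the national liver-and-bile-duct cancer incidence down to
#' advanced-stage (BCLC C) hepatocellular carcinoma: incidence x HCC share
#' x BCLC-C share, rounded to whole patients.
#'
#' @param incidence Annual incident cases.
#' @param hcc_share Fraction that is hepatocellular carcinoma.
#' @param bclc_c_share Fraction of HCC at BCLC stage C.
#' @return Eligible patients per year (integer-valued).
#' @examples
#' eligible_population(27394, 0.50, 0.112)   # 1534
#' @export
eligible_population <- function(incidence, hcc_share, bclc_c_share) {
  if (hcc_share < 0 || hcc_share > 1 || bclc_c_share < 0 || bclc_c_share > 1) {
    abort("shares must lie in [0, 1].")
  }
  round(incidence * hcc_share * bclc_c_share)
}

#' Treatment access-rate ramp
#'
#' Linear uptake schedule: the first-year access rate plus a constant
#' annual increment.
#'
#' @param initial First-year access rate.
#' @param increment Annual increase.
#' @param years Number of projection years.
#' @return Numeric vector of per-year access rates.
#' @examples
#' access_schedule(0.146, 0.065, 5)
#' @export
access_schedule <- function(initial, increment, years) {
  rates <- initial + increment * (seq_len(years) - 1)
  if (any(rates < 0 | rates > 1)) {
    abort("access rates leave [0, 1] within the projection window.")
  }
  rates
}

#' Five-year budget-impact projection
#'
#' Governmental-perspective financial projection of introducing A+B.  The
#' per-patient cost stream is the undiscounted direct medical cost of the
#' A+B strategy from the cohort trace (drug acquisition, administration,
#' monitoring, post-progression supportive care, and any adverse-event
#' cost; direct non-medical costs are excluded and nothing is discounted).
#' Two attribution conventions are offered:
#'
#' * `"initiation"` (default): each starting cohort's full lifetime cost
#'   is booked in its initiation year;
#' * `"calendar"`: each cohort's cost stream is spread over calendar
#'   years, with carry-over from earlier cohorts; `years_out` controls how
#'   far the projection extends (costs beyond it are dropped).
#'
#' Patient counts come from the configured per-year override when present
#' (the published counts), otherwise from
#' `round(eligible_population(...) * access_schedule(...))`.
#'
#' @inheritParams arm_outcomes
#' @param mode Attribution convention, see above.
#' @param patients Optional explicit per-year patient counts, overriding
#'   the configuration.
#' @param years_out Projection length in calendar years for
#'   `mode = "calendar"` (default: the access-ramp years).
#' @return A tibble of class `hcc_budget` with columns `year`,
#'   `access_rate`, `patients`, `cost_usd`, plus attributes
#'   `per_patient_cost` (lifetime, USD), `mode` and `eligible`.
#' @export
project_budget <- function(config, life_table = make_life_table(),
                           mode = c("initiation", "calendar"),
                           patients = NULL, years_out = NULL) {
  config <- validate_config(config)
  mode <- match.arg(mode)
  b <- config$budget
  eligible <- eligible_population(b$incidence_per_year, b$hcc_share,
                                  b$bclc_c_share)
  rates <- access_schedule(b$initial_access, b$access_increment, b$years)
  patients <- patients %||% b$patients_per_year %||% round(eligible * rates)
  if (length(patients) != b$years) {
    abort("`patients` must have one entry per projection year.")
  }

  # Undiscounted per-cycle direct medical cost stream per A+B patient.
  ctx <- .model_context(config, life_table)
  d <- param_means(config)
  sv <- .schedule_vectors(ctx, d, "A+B")
  core <- .markov_core(sv$p_progress, sv$p_death_disease, ctx$bg, ctx$H)
  C <- length(core$pf) - 1L
  idx <- seq_len(C)
  pf <- core$pf[idx]; pr <- core$pr[idx]
  labs <- d$cost_lab_inr + d$cost_lab_afp + d$cost_lab_lft + d$cost_lab_cbc
  stream <- d$cost_drug_month * pf +
    d$cost_admin_month * pf +
    labs * pf * ctx$mask_labs[idx] +
    d$cost_ct_scan * pf * ctx$mask_ct[idx] +
    d$cost_chest_scan * pf * ctx$mask_chest[idx] +
    d$cost_bsc_month * pr
  stream[1] <- stream[1] + ctx$s$ae_cost_oneoff
  lifetime <- sum(stream)

  if (mode == "initiation") {
    years <- seq_len(b$years)
    cost <- patients * lifetime
  } else {
    years_out <- years_out %||% b$years
    # cost of one patient's m-th year on the program
    yearly <- vapply(seq_len(ceiling(C / 12)), function(m) {
      sum(stream[((m - 1) * 12 + 1):min(m * 12, C)])
    }, numeric(1))
    years <- seq_len(years_out)
    cost <- vapply(years, function(k) {
      start_years <- seq_len(min(k, b$years))
      sum(vapply(start_years, function(j) {
        m <- k - j + 1
        if (m <= length(yearly)) patients[j] * yearly[m] else 0
      }, numeric(1)))
    }, numeric(1))
    rates <- c(rates, rep(NA_real_, years_out - b$years))[years]
    patients <- c(patients, rep(0, max(0, years_out - b$years)))[years]
  }
  out <- tibble::tibble(year = years, access_rate = rates,
                        patients = patients, cost_usd = cost)
  attr(out, "per_patient_cost") <- lifetime
  attr(out, "mode") <- mode
  attr(out, "eligible") <- eligible
  class(out) <- c("hcc_budget", class(out))
  out
}
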