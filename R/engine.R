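# Precompute everything that does not vary across parameter draws:
# settings, background-mortality vector, discount factors, monitoring
# charge masks.  Shared by the base case, the tornado sweep and the PSA.
.model_context <- function(config, life_table) {
  s <- config$settings
  H <- s$horizon_cycles
  cyc <- seq_len(H)
  list(
    s = s,
    H = H,
    bg = background_monthly_prob(s$start_age + (cyc - 1) / 12, life_table),
    disc = discount_factor(cyc, s$discount_rate_annual, s$discounting),
    mask_labs = cyc %% s$monitoring$labs == 0,
    mask_ct = cyc %% s$monitoring$ct == 0,
    mask_chest = cyc %% s$monitoring$chest == 0
  )
}

# Piecewise per-cycle probabilities for one draw (no tibble overhead).
.schedule_vectors <- function(ctx, d, arm) {
  cyc <- seq_len(ctx$H)
  pp <- ifelse(cyc < ctx$s$progression_switch_cycle,
               d$p_progress_bsc_early, d$p_progress_bsc_late)
  pd <- ifelse(cyc < ctx$s$death_switch_cycle,
               d$p_death_bsc_early, d$p_death_bsc_late)
  if (arm == "A+B") {
    pp <- apply_hazard_ratio(pp, d$hr_pfs)
    pd <- apply_hazard_ratio(pd, d$hr_os)
  }
  list(p_progress = pp, p_death_disease = pd)
}

# Lifetime outcomes of one arm for one draw: cost components (discounted
# and undiscounted), QALYs, median OS.  This is the single model-evaluation
# kernel behind run_base_case(), one_way_sa() and run_psa(); the
# trace-plus-cost_schedule route (run_trace() + accumulate_costs()) is the
# slower, fully-tabular equivalent and the test suite checks the two agree.
.arm_value <- function(ctx, d, arm, discount_override = NULL) {
  sv <- .schedule_vectors(ctx, d, arm)
  core <- .markov_core(sv$p_progress, sv$p_death_disease, ctx$bg, ctx$H)
  C <- length(core$pf) - 1L
  idx <- seq_len(C)
  hc <- ctx$s$half_cycle_correction
  pf <- if (hc) (core$pf[idx] + core$pf[idx + 1]) / 2 else core$pf[idx]
  pr <- if (hc) (core$pr[idx] + core$pr[idx + 1]) / 2 else core$pr[idx]
  alive <- pf + pr
  disc <- if (is.null(discount_override)) {
    ctx$disc[idx]
  } else {
    discount_factor(idx, discount_override, ctx$s$discounting)
  }
  labs <- d$cost_lab_inr + d$cost_lab_afp + d$cost_lab_lft + d$cost_lab_cbc
  non_med_rate <- d$cost_travel_month + d$cost_food_month +
    d$cost_caregiver_month
  sum2 <- function(occ, f, mask = NULL) {
    if (is.null(mask)) sum(occ * f) else sum(occ[mask] * f[mask])
  }
  one_pass <- function(f) {
    if (arm == "A+B") {
      c(
        drug = d$cost_drug_month * sum2(pf, f),
        administration = d$cost_admin_month * sum2(pf, f),
        monitoring = labs * sum2(pf, f, ctx$mask_labs[idx]) +
          d$cost_ct_scan * sum2(pf, f, ctx$mask_ct[idx]) +
          d$cost_chest_scan * sum2(pf, f, ctx$mask_chest[idx]),
        bsc = d$cost_bsc_month * sum2(pr, f),
        ae = ctx$s$ae_cost_oneoff,
        non_medical = non_med_rate * sum2(alive, f)
      )
    } else {
      c(drug = 0, administration = 0, monitoring = 0,
        bsc = d$cost_bsc_month * sum2(alive, f),
        ae = 0,
        non_medical = non_med_rate * sum2(alive, f))
    }
  }
  comp <- one_pass(disc)
  comp_u <- one_pass(rep(1, C))
  qaly <- sum((pf * d$u_progression_free + pr * d$u_progression) / 12 * disc)
  qaly_u <- sum((pf * d$u_progression_free + pr * d$u_progression) / 12)
  alive_end <- core$pf + core$pr
  below <- which(alive_end < 0.5)
  medical <- c("drug", "administration", "monitoring", "bsc", "ae")
  list(
    components = comp,
    components_undiscounted = comp_u,
    direct_medical = sum(comp[medical]),
    total = sum(comp),
    direct_medical_undiscounted = sum(comp_u[medical]),
    total_undiscounted = sum(comp_u),
    qaly = qaly,
    qaly_undiscounted = qaly_u,
    life_months = sum(alive),
    median_os = if (length(below)) below[1] - 1L else NA_integer_
  )
}

#' Lifetime outcomes for one arm
#'
#' Convenience wrapper running the full pipeline (transition schedule,
#' cohort trace, cost and QALY accumulation) for a single arm and
#' parameter set, at the configuration's discount settings.
#'
#' @inheritParams build_schedule
#' @param life_table Background-mortality life table.
#' @return A one-row tibble: arm, discounted cost components
#'   (`cost_drug`, `cost_administration`, `cost_monitoring`, `cost_bsc`,
#'   `cost_ae`, `cost_non_medical`), `cost_direct_medical`, `cost_total`,
#'   `qaly`, undiscounted twins, `life_months` (start-of-cycle alive
#'   person-months) and `median_os` (months).
#' @export
arm_outcomes <- function(config, arm = c("BSC", "A+B"), draw = NULL,
                         life_table = make_life_table()) {
  config <- validate_config(config)
  arm <- match.arg(arm)
  ctx <- .model_context(config, life_table)
  v <- .arm_value(ctx, as_draw(config, draw), arm)
  tibble::tibble(
    arm = arm,
    cost_drug = v$components[["drug"]],
    cost_administration = v$components[["administration"]],
    cost_monitoring = v$components[["monitoring"]],
    cost_bsc = v$components[["bsc"]],
    cost_ae = v$components[["ae"]],
    cost_non_medical = v$components[["non_medical"]],
    cost_direct_medical = v$direct_medical,
    cost_total = v$total,
    qaly = v$qaly,
    cost_direct_medical_undiscounted = v$direct_medical_undiscounted,
    cost_total_undiscounted = v$total_undiscounted,
    qaly_undiscounted = v$qaly_undiscounted,
    life_months = v$life_months,
    median_os = v$median_os
  )
}
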