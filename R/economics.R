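#' Per-cycle discount factor
#'
#' Implements annual-step discounting with the first year exempt: every
#' cycle in year `y = ceiling(cycle / 12)` is discounted by
#' `(1 + rate)^-(y - 1)`, so cycles 1-12 carry factor 1 and discounting
#' starts beyond the one-year mark.  The `"per_cycle"` method compounds
#' continuously-in-cycles instead, `(1 + rate)^(-(cycle - 1) / 12)`, and is
#' provided as a sensitivity switch.
#'
#' @param cycle Cycle index (1-based).
#' @param rate Annual discount rate (>= 0).
#' @param method `"annual_step"` (default) or `"per_cycle"`.
#' @return Discount factor(s) in `(0, 1]`.
#' @examples
#' discount_factor(12, 0.03)  # 1
#' discount_factor(13, 0.03)  # 1 / 1.03
#' @export
discount_factor <- function(cycle, rate, method = c("annual_step", "per_cycle")) {
  method <- match.arg(method)
  if (any(cycle < 1)) abort("`cycle` is 1-based.")
  if (rate < 0) abort("`rate` must be >= 0.")
  switch(method,
    annual_step = (1 + rate)^-(ceiling(cycle / 12) - 1),
    per_cycle = (1 + rate)^(-(cycle - 1) / 12)
  )
}

#' Arm-specific cost schedule
#'
#' Tabulates every cost item the arm incurs: which state it attaches to
#' (`"progression_free"`, `"progression"`, or `"alive"` for either alive
#' state), its monthly amount, its charging period in cycles, and whether
#' it is a one-off at model entry.  On the A+B arm, drug acquisition,
#' administration and monitoring (labs every cycle, CT every 2, chest scan
#' every 3) apply while progression-free (on treatment); after progression
#' patients move to best supportive care.  The BSC arm's monthly BSC cost
#' is a single bundled estimate applied in both alive states.  Direct
#' non-medical costs (travel, food, caregiver productivity) accrue in
#' every alive state on both arms.  An optional adverse-event management
#' cost is charged once at entry on the A+B arm.
#'
#' @inheritParams build_schedule
#' @return A tibble with columns `component`, `item`, `state`, `amount`,
#'   `every`, `oneoff`.
#' @export
cost_schedule <- function(config, arm = c("BSC", "A+B"), draw = NULL) {
  config <- validate_config(config)
  arm <- match.arg(arm)
  d <- as_draw(config, draw)
  s <- config$settings
  row <- function(component, item, state, amount, every = 1, oneoff = FALSE) {
    tibble::tibble(component = component, item = item, state = state,
                   amount = amount, every = every, oneoff = oneoff)
  }
  non_medical <- dplyr::bind_rows(
    row("non_medical", "travel", "alive", d$cost_travel_month),
    row("non_medical", "food", "alive", d$cost_food_month),
    row("non_medical", "caregiver", "alive", d$cost_caregiver_month)
  )
  if (arm == "BSC") {
    return(dplyr::bind_rows(
      row("bsc", "best_supportive_care", "alive", d$cost_bsc_month),
      non_medical
    ))
  }
  dplyr::bind_rows(
    row("drug", "atezolizumab_bevacizumab", "progression_free",
        d$cost_drug_month),
    row("administration", "drug_administration", "progression_free",
        d$cost_admin_month),
    row("monitoring", "lab_inr", "progression_free", d$cost_lab_inr,
        s$monitoring$labs),
    row("monitoring", "lab_afp", "progression_free", d$cost_lab_afp,
        s$monitoring$labs),
    row("monitoring", "lab_lft", "progression_free", d$cost_lab_lft,
        s$monitoring$labs),
    row("monitoring", "lab_cbc", "progression_free", d$cost_lab_cbc,
        s$monitoring$labs),
    row("monitoring", "ct_abdomen", "progression_free", d$cost_ct_scan,
        s$monitoring$ct),
    row("monitoring", "chest_scan", "progression_free", d$cost_chest_scan,
        s$monitoring$chest),
    row("bsc", "post_progression_bsc", "progression", d$cost_bsc_month),
    row("ae", "ae_management", "progression_free", s$ae_cost_oneoff,
        oneoff = TRUE),
    non_medical
  )
}

# Start-of-cycle occupancy weights for cycles 1..C of a trace (optionally
# averaged with end-of-cycle occupancy under the half-cycle correction).
.cycle_weights <- function(trace, half_cycle = FALSE) {
  C <- max(trace$cycle)
  start <- trace$cycle < C          # rows 0..C-1
  end <- trace$cycle >= 1           # rows 1..C
  w <- function(col) {
    if (half_cycle) (trace[[col]][start] + trace[[col]][end]) / 2
    else trace[[col]][start]
  }
  list(
    C = C,
    progression_free = w("progression_free"),
    progression = w("progression"),
    alive = w("progression_free") + w("progression")
  )
}

#' Accumulate discounted costs over a trace
#'
#' Each cycle contributes the occupancy-weighted sum of the arm's cost
#' items, using start-of-cycle occupancy (events pay the destination state
#' from the next cycle).  Periodic items charge only on cycles divisible
#' by their period (CT on cycles 2, 4, ...; chest scan on 3, 6, ...).
#' One-off items are charged once at cycle 1, undiscounted.
#'
#' @param trace An `hcc_trace`.
#' @param schedule A cost schedule from [cost_schedule()].
#' @param rate Annual discount rate.
#' @param method Discounting method, see [discount_factor()].
#' @param half_cycle Average start- and end-of-cycle occupancy?
#' @return An object of class `hcc_costs`: a list with `components` (a
#'   tibble of discounted and undiscounted totals for the six components:
#'   drug, administration, monitoring, bsc, ae, non_medical),
#'   `direct_medical`, `total`, and their undiscounted twins.
#' @export
accumulate_costs <- function(trace, schedule, rate = 0.03,
                             method = c("annual_step", "per_cycle"),
                             half_cycle = FALSE) {
  method <- match.arg(method)
  w <- .cycle_weights(trace, half_cycle)
  cyc <- seq_len(w$C)
  disc <- discount_factor(cyc, rate, method)
  item_total <- function(state, amount, every, oneoff, discounted) {
    if (oneoff) return(amount)           # cycle 1, exempt from discounting
    occ <- w[[state]]
    charged <- cyc %% every == 0
    f <- if (discounted) disc else 1
    amount * sum(occ[charged] * (if (discounted) disc[charged] else 1))
  }
  comp <- schedule |>
    dplyr::mutate(
      discounted = purrr::pmap_dbl(
        list(.data$state, .data$amount, .data$every, .data$oneoff),
        item_total, discounted = TRUE),
      undiscounted = purrr::pmap_dbl(
        list(.data$state, .data$amount, .data$every, .data$oneoff),
        item_total, discounted = FALSE)
    ) |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(discounted = sum(.data$discounted),
                     undiscounted = sum(.data$undiscounted))
  all_components <- c("drug", "administration", "monitoring", "bsc", "ae",
                      "non_medical")
  comp <- tibble::tibble(component = all_components) |>
    dplyr::left_join(comp, by = "component") |>
    dplyr::mutate(dplyr::across(c("discounted", "undiscounted"),
                                ~ dplyr::coalesce(.x, 0)))
  medical <- comp$component != "non_medical"
  structure(
    list(
      components = comp,
      direct_medical = sum(comp$discounted[medical]),
      total = sum(comp$discounted),
      direct_medical_undiscounted = sum(comp$undiscounted[medical]),
      total_undiscounted = sum(comp$undiscounted),
      arm = attr(trace, "arm")
    ),
    class = "hcc_costs"
  )
}

#' @export
print.hcc_costs <- function(x, ...) {
  cat(sprintf("<hcc_costs%s>\n",
              if (!is.null(x$arm)) paste0(": ", x$arm) else ""))
  print(x$components)
  cat(sprintf("direct medical %.0f, total %.0f (undiscounted %.0f / %.0f) USD\n",
              x$direct_medical, x$total,
              x$direct_medical_undiscounted, x$total_undiscounted))
  invisible(x)
}

#' Accumulate quality-adjusted life years over a trace
#'
#' Each cycle contributes `(occ_PF * u_pf + occ_prog * u_prog) / 12` times
#' its discount factor, with start-of-cycle occupancy.
#'
#' @inheritParams accumulate_costs
#' @param u_pf,u_prog State utilities in `[0, 1]`.
#' @return Discounted QALYs (a single number).
#' @export
accumulate_qalys <- function(trace, u_pf, u_prog, rate = 0.03,
                             method = c("annual_step", "per_cycle"),
                             half_cycle = FALSE) {
  method <- match.arg(method)
  if (u_pf < 0 || u_pf > 1 || u_prog < 0 || u_prog > 1) {
    abort("utilities must lie in [0, 1].")
  }
  w <- .cycle_weights(trace, half_cycle)
  disc <- discount_factor(seq_len(w$C), rate, method)
  sum((w$progression_free * u_pf + w$progression * u_prog) / 12 * disc)
}

#' Drug-acquisition share of direct medical cost
#'
#' @param b An `hcc_costs` breakdown.
#' @return Percentage of the discounted direct medical total attributable
#'   to drug acquisition.
#' @export
drug_cost_share <- function(b) {
  if (!inherits(b, "hcc_costs")) abort("`b` must be an `hcc_costs` object.")
  if (b$direct_medical <= 0) abort("direct medical cost is zero.")
  drug <- b$components$discounted[b$components$component == "drug"]
  100 * drug / b$direct_medical
}
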