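# Merge a (partial) parameter draw onto the parameter means.
as_draw <- function(config, draw = NULL) {
  means <- param_means(config)
  if (is.null(draw)) return(means)
  draw <- as.list(draw)
  draw$.draw <- NULL
  unknown <- setdiff(names(draw), names(means))
  if (length(unknown)) {
    abort(paste0("draw contains unknown parameter(s): ",
                 paste(unknown, collapse = ", ")))
  }
  modifyList(means, draw)
}

#' Build an arm-specific transition schedule
#'
#' Produces the per-cycle monthly probabilities of progression (from the
#' progression-free state) and of disease-specific death (from either
#' alive state).  Both are piecewise constant: progression switches value
#' at the configured cycle (base case: 0.29 for months 1-6, 0.24 after)
#' and disease death likewise (0.17 for months 1-12, 0.10 after).  The BSC
#' arm uses these published probabilities verbatim; the A+B arm passes
#' them through [apply_hazard_ratio()] with the draw's `hr_pfs` and
#' `hr_os`.
#'
#' @param config An `hcc_config`.
#' @param arm `"BSC"` or `"A+B"`.
#' @param draw Optional named list / one-row tibble of parameter values
#'   overriding the means (e.g. one row of [sample_parameters()]).
#' @return A tibble of class `hcc_schedule` with columns `cycle`,
#'   `p_progress`, `p_death_disease` and an `arm` attribute.
#' @export
build_schedule <- function(config, arm = c("BSC", "A+B"), draw = NULL) {
  config <- validate_config(config)
  arm <- match.arg(arm)
  d <- as_draw(config, draw)
  s <- config$settings
  H <- s$horizon_cycles
  cycle <- seq_len(H)
  p_prog <- ifelse(cycle < s$progression_switch_cycle,
                   d$p_progress_bsc_early, d$p_progress_bsc_late)
  p_death <- ifelse(cycle < s$death_switch_cycle,
                    d$p_death_bsc_early, d$p_death_bsc_late)
  if (arm == "A+B") {
    p_prog <- apply_hazard_ratio(p_prog, d$hr_pfs)
    p_death <- apply_hazard_ratio(p_death, d$hr_os)
  }
  out <- tibble::tibble(cycle = cycle, p_progress = p_prog,
                        p_death_disease = p_death)
  attr(out, "arm") <- arm
  class(out) <- c("hcc_schedule", class(out))
  out
}

# Cohort recursion over the three states.  Vectors are indexed so that
# element c + 1 is the occupancy after c cycles (element 1 = model entry).
# Stops early once the alive fraction is below `eps`.
.markov_core <- function(p_progress, p_death_disease, bg, horizon,
                         eps = 1e-9) {
  pf <- numeric(horizon + 1); pr <- numeric(horizon + 1)
  dead <- numeric(horizon + 1); nd <- numeric(horizon + 1)
  pf[1] <- 1
  last <- horizon
  for (c in seq_len(horizon)) {
    p_death_total <- 1 - (1 - p_death_disease[c]) * (1 - bg[c])
    if (p_progress[c] + p_death_total > 1 + 1e-12) {
      abort(sprintf(
        "infeasible schedule at cycle %d: p_progress + total death prob = %.4f > 1",
        c, p_progress[c] + p_death_total))
    }
    deaths <- (pf[c] + pr[c]) * p_death_total
    pf[c + 1] <- pf[c] * (1 - p_progress[c] - p_death_total)
    pr[c + 1] <- pr[c] * (1 - p_death_total) + pf[c] * p_progress[c]
    dead[c + 1] <- dead[c] + deaths
    nd[c + 1] <- deaths
    if (pf[c + 1] + pr[c + 1] < eps) {
      last <- c
      break
    }
  }
  keep <- seq_len(last + 1)
  list(pf = pf[keep], pr = pr[keep], dead = dead[keep], new_deaths = nd[keep])
}

#' Run the cohort trace
#'
#' Propagates a closed cohort (entering entirely progression-free) through
#' the three-state model one monthly cycle at a time.  Disease-specific
#' death applies identically from both alive states and is combined with
#' age-specific background mortality as independent competing
#' probabilities; from the progression-free state the exits
#' \{progress, die\} are mutually exclusive with the stay probability as the
#' complement.  The cohort ages by 1/12 year per cycle for the life-table
#' lookup.  The trace runs to the configured horizon or until the alive
#' fraction falls below `1e-9`, whichever comes first.
#'
#' @param schedule A transition schedule from [build_schedule()].
#' @param life_table A life table (default [make_life_table()]) supplying
#'   background mortality; pass a zero table to switch it off.
#' @param config The `hcc_config` the schedule was built from.
#' @return A tibble of class `hcc_trace` with columns `cycle` (0 = entry),
#'   `age`, `progression_free`, `progression`, `dead`, `new_deaths`,
#'   `alive`, and the arm label as an attribute.  Occupancies at cycle `c`
#'   are evaluated at the end of cycle `c`.
#' @export
run_trace <- function(schedule, life_table = make_life_table(), config) {
  config <- validate_config(config)
  H <- nrow(schedule)
  start_age <- config$settings$start_age
  bg <- background_monthly_prob(start_age + (seq_len(H) - 1) / 12, life_table)
  core <- .markov_core(schedule$p_progress, schedule$p_death_disease, bg, H)
  cycles <- seq_along(core$pf) - 1L
  out <- tibble::tibble(
    cycle = cycles,
    age = start_age + cycles / 12,
    progression_free = core$pf,
    progression = core$pr,
    dead = core$dead,
    new_deaths = core$new_deaths,
    alive = core$pf + core$pr
  )
  attr(out, "arm") <- attr(schedule, "arm")
  class(out) <- c("hcc_trace", class(out))
  out
}

#' Median overall survival of a trace
#'
#' @param trace An `hcc_trace`.
#' @return The smallest cycle index (months) at which the alive fraction
#'   drops below 0.5, or `NA` (with a warning) if the median is not
#'   reached within the simulated horizon.
#' @examples
#' cfg <- default_config()
#' lt <- make_life_table()
#' median_survival(run_trace(build_schedule(cfg, "BSC"), lt, cfg))   # 4
#' median_survival(run_trace(build_schedule(cfg, "A+B"), lt, cfg))   # 10
#' @export
median_survival <- function(trace) {
  below <- which(trace$alive < 0.5)
  if (!length(below)) {
    rlang::warn("median survival not reached within the simulated horizon.")
    return(NA_integer_)
  }
  as.integer(trace$cycle[below[1]])
}

#' Person-time spent in a state
#'
#' Sums end-of-cycle occupancy over cycles 1 and later, optionally
#' weighting each cycle by its discount factor.  Note the economic
#' accumulators ([accumulate_costs()], [accumulate_qalys()]) use
#' start-of-cycle occupancy instead; this helper is a summary of the trace
#' as stored.
#'
#' @param trace An `hcc_trace`.
#' @param state One of `"progression_free"`, `"progression"`, `"dead"`,
#'   `"alive"`.
#' @param discounted Apply per-cycle discount factors?
#' @param rate Annual discount rate used when `discounted = TRUE`.
#' @return Person-months in the state.
#' @export
state_time <- function(trace, state = c("progression_free", "progression",
                                        "dead", "alive"),
                       discounted = FALSE, rate = 0.03) {
  state <- match.arg(state)
  rows <- trace$cycle >= 1
  occ <- trace[[state]][rows]
  w <- if (discounted) discount_factor(trace$cycle[rows], rate) else 1
  sum(occ * w)
}
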