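#' Individual-level microsimulation oracle
#'
#' Simulates `n` independent patients cycle by cycle under exactly the
#' event conventions of the cohort trace (mutually exclusive
#' progress/death exits from progression-free; disease death combined
#' with background mortality as independent competing probabilities).
#' Used as a brute-force cross-check of [run_trace()]: by the law of large
#' numbers the empirical occupancy curves converge on the cohort trace at
#' rate `1/sqrt(n)`.
#'
#' @inheritParams run_trace
#' @param n Number of simulated patients.
#' @param seed RNG seed.
#' @param max_cycles Stop after this many cycles or when everyone is dead
#'   (default: the schedule length).
#' @return A tibble with per-cycle columns `cycle`, `progression_free`,
#'   `progression`, `dead`, `alive` (empirical fractions) and `se_alive`,
#'   the binomial standard error of the alive fraction.
#' @export
microsim <- function(schedule, life_table = make_life_table(), config,
                     n = 10000, seed = 1, max_cycles = NULL) {
  config <- validate_config(config)
  if (n < 1) abort("`n` must be at least 1.")
  H <- max_cycles %||% nrow(schedule)
  start_age <- config$settings$start_age
  bg <- background_monthly_prob(start_age + (seq_len(H) - 1) / 12, life_table)
  PF <- 1L; PR <- 2L; DEAD <- 3L
  withr::with_seed(seed, {
    state <- rep(PF, n)
    rec <- matrix(0, nrow = H + 1, ncol = 3)
    rec[1, ] <- c(1, 0, 0)
    for (c in seq_len(H)) {
      p_death <- 1 - (1 - schedule$p_death_disease[c]) * (1 - bg[c])
      u <- runif(n)
      alive <- state != DEAD
      dies <- alive & u < p_death
      progresses <- state == PF & !dies &
        u < p_death + schedule$p_progress[c]
      state[dies] <- DEAD
      state[progresses] <- PR
      rec[c + 1, ] <- tabulate(state, nbins = 3) / n
      if (all(state == DEAD)) {
        rec <- rec[seq_len(c + 1), , drop = FALSE]
        break
      }
    }
    alive_frac <- rec[, 1] + rec[, 2]
    tibble::tibble(
      cycle = seq_len(nrow(rec)) - 1L,
      progression_free = rec[, 1],
      progression = rec[, 2],
      dead = rec[, 3],
      alive = alive_frac,
      se_alive = sqrt(pmax(alive_frac * (1 - alive_frac), 0) / n)
    )
  })
}

#' Randomly perturbed configuration
#'
#' Jitters every parameter mean by an independent uniform factor within
#' `1 +/- amount`, then clamps back to each family's validity region
#' (probabilities below one jointly feasible for the transition pairs,
#' beta means compatible with their SE).  Intended for metamorphic and
#' property-style testing, not for analysis.
#'
#' @param base A valid `hcc_config`.
#' @param seed RNG seed.
#' @param amount Maximum relative perturbation (default 0.2); zero
#'   returns the base configuration unchanged.
#' @return A validated `hcc_config`.
#' @export
perturbed_config <- function(base, seed = 1, amount = 0.2) {
  base <- validate_config(base)
  if (amount < 0) abort("`amount` must be non-negative.")
  if (amount == 0) return(base)
  params <- base$parameters
  withr::with_seed(seed, {
    factor <- runif(nrow(params), 1 - amount, 1 + amount)
    params$mean <- params$mean * factor
  })
  # clamp back inside each family's validity region
  prob_like <- params$role == "transition_prob" | params$family == "beta"
  params$mean[prob_like] <- pmin(params$mean[prob_like], 0.95)
  beta <- params$family == "beta"
  params$se[beta] <- pmin(
    params$se[beta],
    0.9 * sqrt(params$mean[beta] * (1 - params$mean[beta]))
  )
  # keep the per-cycle exit probabilities jointly feasible
  pp <- params$name %in% c("p_progress_bsc_early", "p_progress_bsc_late")
  pd <- params$name %in% c("p_death_bsc_early", "p_death_bsc_late")
  total <- max(params$mean[pp]) + max(params$mean[pd])
  if (total > 0.98) {
    shrink <- 0.98 / total
    params$mean[pp | pd] <- params$mean[pp | pd] * shrink
  }
  default_config(parameters = params, settings = base$settings,
                 budget = base$budget)
}
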