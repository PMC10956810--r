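#' Convert a cumulative probability to a constant event rate
#'
#' Inverts the exponential survival relationship: a probability `p` of the
#' event occurring over duration `t` corresponds to a constant rate
#' `-log(1 - p) / t` per unit of `t`.
#'
#' @param p Event probability over the interval; must satisfy `0 <= p < 1`.
#' @param t Interval length in the time unit the rate should be expressed in
#'   (default 1).
#' @return Event rate per unit time.  Vectorised over `p` and `t`.
#' @seealso [rate_to_prob()] for the inverse, [apply_hazard_ratio()] for
#'   rate-scale hazard-ratio adjustment of probabilities.
#' @examples
#' prob_to_rate(0.29)            # monthly progression probability -> rate
#' rate_to_prob(prob_to_rate(0.29))
#' @export
prob_to_rate <- function(p, t = 1) {
  if (any(!is.finite(p))) abort("`p` must be finite.")
  if (any(p == 1)) abort("`p` = 1 implies an infinite event rate.")
  if (any(p < 0 | p > 1)) abort("`p` must be a probability in [0, 1).")
  if (any(t <= 0)) abort("`t` must be positive.")
  -log(1 - p) / t
}

#' Convert a constant event rate to a cumulative probability
#'
#' @param r Event rate per unit time; must be non-negative.
#' @param t Interval length (default 1).
#' @return Probability that the event occurs within `t`: `1 - exp(-r * t)`.
#' @export
rate_to_prob <- function(r, t = 1) {
  if (any(!is.finite(r) & !is.infinite(r))) abort("`r` must be numeric.")
  if (any(r < 0)) abort("`r` must be non-negative.")
  if (any(t <= 0)) abort("`t` must be positive.")
  1 - exp(-r * t)
}

#' Apply a hazard ratio to a per-cycle probability
#'
#' Converts the reference probability to the rate scale, multiplies by the
#' hazard ratio, and converts back, which collapses to
#' `1 - (1 - p_ref)^hr`.  This is the standard way decision models apply a
#' treatment-effect hazard ratio to the comparator arm's per-cycle
#' transition probabilities.
#'
#' @param p_ref Reference-arm per-cycle probability, `0 <= p_ref < 1`.
#' @param hr Hazard ratio (> 0); values below 1 reduce the probability.
#' @return Adjusted per-cycle probability.
#' @examples
#' apply_hazard_ratio(0.17, 0.40)  # BSC monthly death prob under HR 0.40
#' @export
apply_hazard_ratio <- function(p_ref, hr) {
  if (any(p_ref < 0 | p_ref >= 1)) abort("`p_ref` must be in [0, 1).")
  if (any(hr <= 0)) abort("`hr` must be positive.")
  1 - (1 - p_ref)^hr
}

#' Combine two independent per-cycle probabilities
#'
#' Complement-product combination of two competing, independent event
#' probabilities over the same cycle, used to merge disease-specific death
#' with background (other-cause) mortality.
#'
#' @param p_a,p_b Probabilities in `[0, 1]`.
#' @return `1 - (1 - p_a) * (1 - p_b)`; symmetric and never smaller than
#'   either input.
#' @export
combine_independent <- function(p_a, p_b) {
  if (any(p_a < 0 | p_a > 1) || any(p_b < 0 | p_b > 1)) {
    abort("probabilities must lie in [0, 1].")
  }
  1 - (1 - p_a) * (1 - p_b)
}

#' Convert a survival proportion at a landmark time to a per-cycle probability
#'
#' Given a cumulative event probability `P` observed at `T_months`, returns
#' the implied constant per-cycle (monthly) transition probability.  Two
#' interpretations of the time denominator are provided:
#'
#' * `"per_month"`: the event rate is `-log(1 - P) / T_months` per month and
#'   the returned value is the one-month probability.  This reading is the
#'   one consistent with the model's published base-case monthly
#'   probabilities.
#' * `"literal"`: the denominator is `T_months / 12`, i.e. the rate is
#'   expressed per year, and the returned value is `1 - exp(-rate)` —
#'   effectively a 12-month probability.  Kept so users can reproduce the
#'   printed formula exactly as written.
#'
#' The base-case analysis does not call this helper: the monthly
#' probabilities are model inputs taken directly from the parameter table.
#'
#' @param P Cumulative event probability at the landmark, `0 <= P < 1`.
#' @param T_months Landmark time in months (> 0).
#' @param interpretation `"per_month"` (default) or `"literal"`.
#' @return Per-cycle transition probability.
#' @export
survival_to_cycle_prob <- function(P, T_months,
                                   interpretation = c("per_month", "literal")) {
  interpretation <- match.arg(interpretation)
  t <- switch(interpretation,
    per_month = T_months,
    literal   = T_months / 12
  )
  rate_to_prob(prob_to_rate(P, t), 1)
}
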