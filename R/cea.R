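#' Incremental cost-effectiveness ratio
#'
#' @param cost1,qaly1 Cost and effectiveness of the intervention.
#' @param cost0,qaly0 Cost and effectiveness of the comparator.
#' @return A tibble with `delta_cost`, `delta_qaly`, `icer` and `status`:
#'   `"ok"` when the ratio is meaningful, `"dominant"` (cheaper and more
#'   effective), `"dominated"` (costlier and less effective), or
#'   `"undefined"` when the effect difference is numerically zero.  The
#'   `icer` is `NA` in the three flagged cases.  Vectorised.
#' @examples
#' icer(48669, 1.2552, 3312, 0.4243)
#' @export
icer <- function(cost1, qaly1, cost0, qaly0) {
  dc <- cost1 - cost0
  de <- qaly1 - qaly0
  status <- dplyr::case_when(
    abs(de) < 1e-12 ~ "undefined",
    de > 0 & dc < 0 ~ "dominant",
    de < 0 & dc > 0 ~ "dominated",
    TRUE ~ "ok"
  )
  tibble::tibble(
    delta_cost = dc,
    delta_qaly = de,
    icer = ifelse(status == "ok", dc / de, NA_real_),
    status = status
  )
}

#' Deterministic base-case cost-effectiveness analysis
#'
#' Runs both arms at the parameter means (or at a supplied draw) and
#' computes the incremental comparison of A+B against BSC.
#'
#' @inheritParams arm_outcomes
#' @return An object of class `hcc_cea`: list with `arms` (two-row tibble
#'   from [arm_outcomes()]) and `incremental` (one row from [icer()]).
#'   `tidy()` returns the per-arm tibble, `glance()` a one-row summary.
#' @examples
#' \donttest{
#' res <- run_base_case(default_config())
#' glance(res)
#' }
#' @export
run_base_case <- function(config, life_table = make_life_table(),
                          draw = NULL) {
  config <- validate_config(config)
  arms <- dplyr::bind_rows(
    arm_outcomes(config, "BSC", draw, life_table),
    arm_outcomes(config, "A+B", draw, life_table)
  )
  inc <- icer(arms$cost_total[2], arms$qaly[2],
              arms$cost_total[1], arms$qaly[1])
  structure(list(arms = arms, incremental = inc, config = config),
            class = "hcc_cea")
}

#' @export
print.hcc_cea <- function(x, ...) {
  cat("<hcc_cea> deterministic base case\n")
  print(dplyr::select(x$arms, "arm", "cost_total", "qaly", "median_os"))
  with(x$incremental, cat(sprintf(
    "incremental cost %.0f USD, incremental QALY %.4f, ICER %s USD/QALY [%s]\n",
    delta_cost, delta_qaly,
    ifelse(is.na(icer), "-", format(round(icer), big.mark = ",")), status)))
  invisible(x)
}

#' @export
#' @method tidy hcc_cea
tidy.hcc_cea <- function(x, ...) x$arms

#' @export
#' @method glance hcc_cea
glance.hcc_cea <- function(x, ...) {
  tibble::tibble(
    cost_ab = x$arms$cost_total[2], qaly_ab = x$arms$qaly[2],
    cost_bsc = x$arms$cost_total[1], qaly_bsc = x$arms$qaly[1],
    median_os_ab = x$arms$median_os[2], median_os_bsc = x$arms$median_os[1],
    delta_cost = x$incremental$delta_cost,
    delta_qaly = x$incremental$delta_qaly,
    icer = x$incremental$icer,
    status = x$incremental$status
  )
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the deterministic comparison with each non-fixed parameter in
#' turn set to the lower and upper bound of its normal-approximation 95%
#' confidence interval ([ci_bounds()]), all other parameters at their
#' means, and additionally sweeps the annual discount rate over 0% and 6%.
#' Entries are sorted by the ICER swing, largest first.
#'
#' @inheritParams arm_outcomes
#' @param discount_range Two discount rates for the discount-rate entry
#'   (default `c(0, 0.06)`).
#' @return A tibble of class `hcc_tornado`: `parameter`, `low`, `high`
#'   (input values), `icer_low`, `icer_high`, `icer_base`, `swing`, and a
#'   logical `flagged` marking bounds where the model was infeasible or
#'   the ICER undefined.
#' @export
one_way_sa <- function(config, life_table = make_life_table(),
                       discount_range = c(0, 0.06)) {
  config <- validate_config(config)
  ctx <- .model_context(config, life_table)
  means <- param_means(config)
  eval_icer <- function(d, rate_override = NULL) {
    tryCatch({
      ab <- .arm_value(ctx, d, "A+B", discount_override = rate_override)
      bsc <- .arm_value(ctx, d, "BSC", discount_override = rate_override)
      icer(ab$total, ab$qaly, bsc$total, bsc$qaly)$icer
    }, error = function(e) NA_real_)
  }
  base <- eval_icer(means)
  varying <- config$parameters |> dplyr::filter(.data$family != "fixed")
  bounds <- ci_bounds(varying$mean, varying$se, varying$family)
  rows <- purrr::pmap_dfr(
    list(varying$name, bounds$low, bounds$high),
    function(name, lo, hi) {
      d_lo <- means; d_lo[[name]] <- lo
      d_hi <- means; d_hi[[name]] <- hi
      tibble::tibble(parameter = name, low = lo, high = hi,
                     icer_low = eval_icer(d_lo), icer_high = eval_icer(d_hi))
    }
  )
  rows <- dplyr::bind_rows(rows, tibble::tibble(
    parameter = "discount_rate_annual",
    low = discount_range[1], high = discount_range[2],
    icer_low = eval_icer(means, discount_range[1]),
    icer_high = eval_icer(means, discount_range[2])
  ))
  out <- rows |>
    dplyr::mutate(
      icer_base = base,
      swing = abs(.data$icer_high - .data$icer_low),
      flagged = is.na(.data$icer_low) | is.na(.data$icer_high)
    ) |>
    dplyr::arrange(dplyr::desc(.data$swing))
  class(out) <- c("hcc_tornado", class(out))
  out
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo propagation of all parameter uncertainty: each iteration
#' draws one value per non-fixed parameter from its moment-matched
#' distribution, rebuilds both arms' schedules, runs the cohort model and
#' records costs and QALYs.  Draws yielding an infeasible schedule
#' (per-cycle exit probabilities exceeding one) are redrawn and counted.
#' The full run is reproducible from the seed alone.
#'
#' @inheritParams arm_outcomes
#' @param iterations Number of iterations (default
#'   `config$settings$psa_iterations`, base case 5,000).
#' @param seed RNG seed (default `config$settings$psa_seed`).
#' @return A tibble of class `hcc_psa` with columns `iteration`,
#'   `cost_ab`, `qaly_ab`, `cost_bsc`, `qaly_bsc`, `delta_cost`,
#'   `delta_qaly`, and attributes `seed`, `redraws` and `wtp_thresholds`.
#' @export
run_psa <- function(config, life_table = make_life_table(),
                    iterations = NULL, seed = NULL) {
  config <- validate_config(config)
  iterations <- iterations %||% config$settings$psa_iterations
  seed <- seed %||% config$settings$psa_seed
  ctx <- .model_context(config, life_table)
  redraws <- 0L
  run_one <- function(d) {
    ab <- .arm_value(ctx, d, "A+B")
    bsc <- .arm_value(ctx, d, "BSC")
    c(cost_ab = ab$total, qaly_ab = ab$qaly,
      cost_bsc = bsc$total, qaly_bsc = bsc$qaly)
  }
  out <- withr::with_seed(seed, {
    lnp <- config$settings$lognormal_parametrization
    draws <- as.list(.sample_param_matrix(config$parameters, iterations, lnp))
    res <- matrix(NA_real_, iterations, 4)
    for (i in seq_len(iterations)) {
      d <- lapply(draws, function(col) col[i])
      row <- tryCatch(run_one(d), error = function(e) NULL)
      while (is.null(row)) {
        redraws <<- redraws + 1L
        d <- as.list(.sample_param_matrix(config$parameters, 1, lnp)[1, ])
        row <- tryCatch(run_one(d), error = function(e) NULL)
      }
      res[i, ] <- row
    }
    res
  })
  psa <- tibble::tibble(
    iteration = seq_len(iterations),
    cost_ab = out[, 1], qaly_ab = out[, 2],
    cost_bsc = out[, 3], qaly_bsc = out[, 4],
    delta_cost = out[, 1] - out[, 3],
    delta_qaly = out[, 2] - out[, 4]
  )
  attr(psa, "seed") <- seed
  attr(psa, "redraws") <- redraws
  attr(psa, "wtp_thresholds") <- config$settings$wtp_thresholds
  class(psa) <- c("hcc_psa", class(psa))
  psa
}

#' @export
#' @method tidy hcc_psa
tidy.hcc_psa <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  out
}

#' Summarise a probabilistic analysis
#'
#' The headline probabilistic ICER is the ratio of the Monte-Carlo mean
#' incremental cost to the mean incremental QALY (the expectation of the
#' ratio is not a meaningful estimator).
#'
#' @param x An `hcc_psa`.
#' @param ... Unused.
#' @return One-row tibble: iteration count, seed, redraw count, mean
#'   per-arm costs/QALYs, mean incrementals, and `icer` (ratio of means).
#' @export
#' @method glance hcc_psa
glance.hcc_psa <- function(x, ...) {
  tibble::tibble(
    iterations = nrow(x),
    seed = attr(x, "seed"),
    redraws = attr(x, "redraws"),
    mean_cost_ab = mean(x$cost_ab), mean_qaly_ab = mean(x$qaly_ab),
    mean_cost_bsc = mean(x$cost_bsc), mean_qaly_bsc = mean(x$qaly_bsc),
    mean_delta_cost = mean(x$delta_cost),
    mean_delta_qaly = mean(x$delta_qaly),
    icer = mean(x$delta_cost) / mean(x$delta_qaly)
  )
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA iterations in
#' which the intervention has strictly positive incremental net monetary
#' benefit, `wtp * delta_qaly - delta_cost > 0` (ties count as not
#' cost-effective).
#'
#' @param psa An `hcc_psa`.
#' @param wtp Willingness-to-pay grid in USD/QALY.  Defaults to 0 to
#'   100,000 in steps of 500 plus the configured thresholds exactly.
#' @return A tibble of class `hcc_ceac` with columns `wtp` and `prob_ce`.
#' @export
ceac <- function(psa, wtp = NULL) {
  if (!nrow(psa)) abort("empty PSA results.")
  if (is.null(wtp)) {
    wtp <- sort(unique(c(seq(0, 100000, by = 500),
                         attr(psa, "wtp_thresholds"))))
  }
  if (!length(wtp)) abort("empty willingness-to-pay grid.")
  out <- tibble::tibble(
    wtp = wtp,
    prob_ce = vapply(wtp, function(l) {
      mean(l * psa$delta_qaly - psa$delta_cost > 0)
    }, numeric(1))
  )
  class(out) <- c("hcc_ceac", class(out))
  out
}
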