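#' @importFrom ggplot2 ggplot aes geom_line geom_area geom_point geom_col
#'   geom_vline geom_hline geom_errorbarh labs scale_y_continuous
#'   scale_x_continuous theme_minimal
NULL

#' Plot a cohort trace
#'
#' State-occupancy curves over the model horizon.
#'
#' @param object An `hcc_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot hcc_trace
autoplot.hcc_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    c("progression_free", "progression", "dead"),
    names_to = "state", values_to = "occupancy"
  )
  long$state <- factor(long$state,
                       c("progression_free", "progression", "dead"))
  ggplot(long, aes(x = .data$cycle, y = .data$occupancy,
                   colour = .data$state)) +
    geom_line() +
    labs(x = "Cycle (months)", y = "Fraction of cohort", colour = NULL,
         title = paste0("Cohort trace",
                        if (!is.null(attr(object, "arm")))
                          paste0(" (", attr(object, "arm"), ")"))) +
    theme_minimal()
}

#' Plot the PSA cost-effectiveness plane
#'
#' Scatter of incremental cost against incremental QALYs across
#' iterations, with the configured willingness-to-pay thresholds drawn as
#' lines through the origin.
#'
#' @param object An `hcc_psa`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot hcc_psa
autoplot.hcc_psa <- function(object, ...) {
  p <- ggplot(tibble::as_tibble(object),
              aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    geom_point(alpha = 0.2, size = 0.6) +
    geom_hline(yintercept = 0, linewidth = 0.2) +
    geom_vline(xintercept = 0, linewidth = 0.2) +
    labs(x = "Incremental QALYs", y = "Incremental cost (USD)",
         title = "Cost-effectiveness plane") +
    theme_minimal()
  for (wtp in attr(object, "wtp_thresholds") %||% numeric()) {
    p <- p + ggplot2::geom_abline(slope = wtp, intercept = 0,
                                  linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param object An `hcc_ceac` (from [ceac()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot hcc_ceac
autoplot.hcc_ceac <- function(object, ...) {
  ggplot(tibble::as_tibble(object), aes(x = .data$wtp, y = .data$prob_ce)) +
    geom_line() +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "Willingness to pay (USD/QALY)",
         y = "Probability cost-effective",
         title = "Cost-effectiveness acceptability curve") +
    theme_minimal()
}

#' Plot a tornado diagram
#'
#' Horizontal bars spanning the ICER range each parameter induces when
#' swept across its confidence bounds, ranked by swing.
#'
#' @param object An `hcc_tornado` (from [one_way_sa()]).
#' @param top Show only the `top` widest bars (default 10).
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot hcc_tornado
autoplot.hcc_tornado <- function(object, top = 10, ...) {
  dat <- tibble::as_tibble(object) |>
    dplyr::filter(!.data$flagged) |>
    dplyr::slice_head(n = top) |>
    dplyr::mutate(parameter = factor(.data$parameter,
                                     rev(.data$parameter)))
  ggplot(dat, aes(y = .data$parameter)) +
    geom_errorbarh(aes(xmin = pmin(.data$icer_low, .data$icer_high),
                       xmax = pmax(.data$icer_low, .data$icer_high)),
                   height = 0.4) +
    geom_vline(aes(xintercept = .data$icer_base), linetype = "dashed") +
    labs(x = "ICER (USD/QALY)", y = NULL, title = "One-way sensitivity") +
    theme_minimal()
}

#' Plot a budget-impact projection
#'
#' @param object An `hcc_budget` (from [project_budget()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot hcc_budget
autoplot.hcc_budget <- function(object, ...) {
  ggplot(tibble::as_tibble(object),
         aes(x = factor(.data$year), y = .data$cost_usd / 1e6)) +
    geom_col(fill = "steelblue") +
    labs(x = "Year", y = "Budget (million USD)",
         title = "Five-year budget impact") +
    theme_minimal()
}
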