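#' Construct and validate a parameter table
#'
#' A parameter table holds every model input with its uncertainty
#' distribution: one row per parameter with columns `name`, `mean`, `se`,
#' `family` (one of `"lognormal"`, `"gamma"`, `"beta"`, `"fixed"`) and
#' `role` (one of `"hazard_ratio"`, `"transition_prob"`, `"cost"`,
#' `"utility"`, `"other"`).  Means are in natural units: USD per month for
#' costs, probabilities per cycle for transitions, ratios for hazard
#' ratios, utility weights on the 0-1 scale.
#'
#' @param params A data frame with the columns above.
#' @return The validated tibble (invisibly unchanged apart from class
#'   coercion).
#' @export
validate_parameters <- function(params) {
  params <- tibble::as_tibble(params)
  needed <- c("name", "mean", "se", "family", "role")
  missing <- setdiff(needed, names(params))
  if (length(missing)) {
    abort(paste0("parameter table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  fam_ok <- params$family %in% c("lognormal", "gamma", "beta", "fixed")
  if (!all(fam_ok)) {
    abort(paste0("unknown distribution family for: ",
                 paste(params$name[!fam_ok], collapse = ", ")))
  }
  role_ok <- params$role %in%
    c("hazard_ratio", "transition_prob", "cost", "utility", "other")
  if (!all(role_ok)) {
    abort(paste0("unknown role for: ",
                 paste(params$name[!role_ok], collapse = ", ")))
  }
  if (anyDuplicated(params$name)) abort("duplicated parameter names.")
  bad_se <- params$family != "fixed" & (is.na(params$se) | params$se < 0)
  if (any(bad_se)) {
    abort(paste0("negative or missing SE for: ",
                 paste(params$name[bad_se], collapse = ", ")))
  }
  beta <- params$family == "beta"
  bad_beta <- beta &
    (params$mean < 0 | params$mean > 1 |
       params$se^2 >= params$mean * (1 - params$mean))
  if (any(bad_beta)) {
    abort(paste0("beta parameter outside [0, 1] or SE too large for: ",
                 paste(params$name[bad_beta], collapse = ", ")))
  }
  pos <- params$family %in% c("gamma", "lognormal")
  if (any(pos & params$mean <= 0)) {
    abort(paste0("gamma/lognormal mean must be positive for: ",
                 paste(params$name[pos & params$mean <= 0], collapse = ", ")))
  }
  params
}

#' Moment-match a distribution to a printed mean and standard error
#'
#' The parameter table reports only a family, a mean and an SE for each
#' uncertain input, so distribution parameters are recovered by matching
#' first and second moments on the natural scale:
#'
#' * gamma: `shape = mean^2 / se^2`, `scale = se^2 / mean`;
#' * beta: method of moments,
#'   `alpha + beta = mean (1 - mean) / se^2 - 1`, `alpha = mean (alpha + beta)`;
#' * lognormal (default `"moments"` parametrisation):
#'   `sdlog = sqrt(log(1 + (se/mean)^2))`,
#'   `meanlog = log(mean) - sdlog^2 / 2`, so the natural-scale mean and SD
#'   equal the printed mean and SE exactly.  The alternative `"naive"`
#'   parametrisation (`meanlog = log(mean)`, `sdlog = se / mean`) is kept
#'   behind the switch because published models sometimes use it; it makes
#'   the printed mean the natural-scale *median*.
#'
#' @param mean,se Natural-scale mean and standard error (vectorised).
#' @param family Distribution family; `"fixed"` is not samplable and is
#'   rejected here.
#' @param lognormal_parametrization `"moments"` (default) or `"naive"`.
#' @return A tibble with columns `family`, `shape`, `scale`, `alpha`,
#'   `beta`, `meanlog`, `sdlog`; entries not applicable to a family are NA.
#' @examples
#' moment_match(489, 49, "gamma")      # shape ~ 99.6, scale ~ 4.91
#' moment_match(0.89, 0.02, "beta")    # alpha ~ 216.9, beta ~ 26.8
#' moment_match(0.40, 0.07, "lognormal")
#' @export
moment_match <- function(mean, se, family,
                         lognormal_parametrization = c("moments", "naive")) {
  lnp <- match.arg(lognormal_parametrization)
  n <- max(length(mean), length(se), length(family))
  mean <- rep_len(mean, n); se <- rep_len(se, n); family <- rep_len(family, n)
  if (any(family == "fixed")) {
    abort("`fixed` parameters have no sampling distribution to match.")
  }
  if (any(!family %in% c("gamma", "beta", "lognormal"))) {
    abort("unknown distribution family.")
  }
  validate_parameters(tibble::tibble(
    name = paste0("p", seq_len(n)), mean = mean, se = se,
    family = family, role = "other"
  ))
  out <- tibble::tibble(
    family = family,
    shape = NA_real_, scale = NA_real_,
    alpha = NA_real_, beta = NA_real_,
    meanlog = NA_real_, sdlog = NA_real_
  )
  g <- family == "gamma"
  out$shape[g] <- mean[g]^2 / se[g]^2
  out$scale[g] <- se[g]^2 / mean[g]
  b <- family == "beta"
  ab <- mean[b] * (1 - mean[b]) / se[b]^2 - 1
  out$alpha[b] <- mean[b] * ab
  out$beta[b] <- (1 - mean[b]) * ab
  l <- family == "lognormal"
  if (lnp == "moments") {
    out$sdlog[l] <- sqrt(log(1 + (se[l] / mean[l])^2))
    out$meanlog[l] <- log(mean[l]) - out$sdlog[l]^2 / 2
  } else {
    out$sdlog[l] <- se[l] / mean[l]
    out$meanlog[l] <- log(mean[l])
  }
  out
}

#' Normal-approximation confidence bounds for a parameter
#'
#' Returns `mean +/- z * se`, truncated to the distribution's support
#' (non-negative for gamma and lognormal, `[0, 1]` for beta).  Parameters
#' of family `"fixed"` collapse to `(mean, mean)`.  Used by the one-way
#' sensitivity analysis, which sweeps each parameter across these bounds.
#'
#' @inheritParams moment_match
#' @param z Normal quantile multiplier (default 1.96, a 95% interval).
#' @return Tibble with columns `low` and `high`.
#' @export
ci_bounds <- function(mean, se, family, z = 1.96) {
  n <- max(length(mean), length(se), length(family))
  mean <- rep_len(mean, n); se <- rep_len(se, n); family <- rep_len(family, n)
  se <- ifelse(family == "fixed", 0, se)
  low <- mean - z * se
  high <- mean + z * se
  support_pos <- family %in% c("gamma", "lognormal")
  low[support_pos] <- pmax(low[support_pos], 0)
  b <- family == "beta"
  low[b] <- pmax(low[b], 0)
  high[b] <- pmin(high[b], 1)
  tibble::tibble(low = low, high = high)
}

# One draw column per parameter; fixed parameters pass through as constants.
.sample_param_matrix <- function(params, n, lognormal_parametrization) {
  draws <- lapply(seq_len(nrow(params)), function(i) {
    p <- params[i, ]
    if (p$family == "fixed" || p$se == 0) return(rep(p$mean, n))
    m <- moment_match(p$mean, p$se, p$family, lognormal_parametrization)
    switch(p$family,
      gamma = rgamma(n, shape = m$shape, scale = m$scale),
      beta = rbeta(n, m$alpha, m$beta),
      lognormal = rlnorm(n, m$meanlog, m$sdlog)
    )
  })
  names(draws) <- params$name
  tibble::as_tibble(draws)
}

#' Draw parameter sets for probabilistic analysis
#'
#' One independent draw per non-fixed parameter from its moment-matched
#' distribution; fixed parameters (and any with `se = 0`) pass through as
#' constants.
#'
#' @param config A model configuration (see [default_config()]).
#' @param n Number of draws (rows).
#' @param seed Optional integer; when supplied the draw is made under
#'   [withr::with_seed()] so the caller's RNG state is untouched and the
#'   result is reproducible.  When `NULL` the current RNG state is used.
#' @return A tibble with `n` rows, a `.draw` index column and one column
#'   per parameter.
#' @export
sample_parameters <- function(config, n = 1, seed = NULL) {
  config <- validate_config(config)
  lnp <- config$settings$lognormal_parametrization
  draw <- if (is.null(seed)) {
    .sample_param_matrix(config$parameters, n, lnp)
  } else {
    withr::with_seed(seed, .sample_param_matrix(config$parameters, n, lnp))
  }
  dplyr::bind_cols(tibble::tibble(.draw = seq_len(n)), draw)
}

# Named list of parameter means, the deterministic "draw".
param_means <- function(config) {
  as.list(setNames(config$parameters$mean, config$parameters$name))
}
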