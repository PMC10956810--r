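test_that("moment matching reproduces the algebraic solutions", {
  g <- moment_match(489, 49, "gamma")
  expect_equal(g$shape, 489^2 / 49^2, tolerance = 1e-12)
  expect_equal(g$scale, 49^2 / 489, tolerance = 1e-12)
  expect_equal(g$shape, 99.59, tolerance = 1e-3)
  expect_equal(g$scale, 4.910, tolerance = 1e-3)

  b <- moment_match(0.89, 0.02, "beta")
  ab <- 0.89 * 0.11 / 0.02^2 - 1
  expect_equal(b$alpha, 0.89 * ab, tolerance = 1e-12)
  expect_equal(b$beta, 0.11 * ab, tolerance = 1e-12)
  expect_equal(b$alpha, 216.9, tolerance = 1e-3)
  expect_equal(b$beta, 26.8, tolerance = 2e-3)

  l <- moment_match(0.40, 0.07, "lognormal")
  expect_equal(l$sdlog, sqrt(log(1 + (0.07 / 0.40)^2)), tolerance = 1e-12)
  expect_equal(l$sdlog, 0.1737, tolerance = 1e-3)
  expect_equal(l$meanlog, log(0.40) - l$sdlog^2 / 2, tolerance = 1e-12)
  expect_equal(l$meanlog, -0.9314, tolerance = 1e-3)
  # the naive parametrisation puts the printed mean at the median instead
  ln <- moment_match(0.40, 0.07, "lognormal",
                     lognormal_parametrization = "naive")
  expect_equal(ln$meanlog, log(0.40))
  expect_equal(ln$sdlog, 0.07 / 0.40)

  expect_error(moment_match(0.29, 0, "fixed"), "fixed")
  expect_error(moment_match(1.2, 0.02, "beta"), "beta")
})

test_that("moment-matched distributions return the printed mean and SE in sample", {
  # sampling cross-check of the algebra, one family each at n = 1e5
  withr::with_seed(21, {
    cases <- list(
      list(mean = 489, se = 49, family = "gamma"),
      list(mean = 0.89, se = 0.02, family = "beta"),
      list(mean = 0.40, se = 0.07, family = "lognormal")
    )
    n <- 1e5
    for (cs in cases) {
      m <- moment_match(cs$mean, cs$se, cs$family)
      x <- switch(cs$family,
        gamma = rgamma(n, shape = m$shape, scale = m$scale),
        beta = rbeta(n, m$alpha, m$beta),
        lognormal = rlnorm(n, m$meanlog, m$sdlog)
      )
      expect_lt(abs(mean(x) - cs$mean), 4 * cs$se / sqrt(n))
      expect_lt(abs(sd(x) - cs$se), 4 * cs$se / sqrt(n))
    }
  })
})

test_that("confidence bounds bracket the mean and respect support", {
  b <- ci_bounds(0.40, 0.07, "lognormal")
  expect_equal(b$low, 0.2628, tolerance = 1e-10)
  expect_equal(b$high, 0.5372, tolerance = 1e-10)
  expect_equal(ci_bounds(0.29, NA, "fixed"), tibble::tibble(low = 0.29, high = 0.29))
  capped <- ci_bounds(0.89, 0.08, "beta")
  expect_equal(capped$high, 1.0)
  floor <- ci_bounds(3, 2.2, "gamma")
  expect_equal(floor$low, 0)
  # low <= mean <= high across the whole base-case table
  p <- default_parameters()
  bb <- ci_bounds(p$mean, p$se, p$family)
  expect_true(all(bb$low <= p$mean + 1e-12 & p$mean <= bb$high + 1e-12))
})

test_that("parameter sampling is reproducible and degenerate at zero SE", {
  cfg <- test_config()
  d1 <- sample_parameters(cfg, n = 5, seed = 99)
  d2 <- sample_parameters(cfg, n = 5, seed = 99)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 5)
  # fixed parameters pass through
  expect_true(all(d1$p_progress_bsc_early == 0.29))
  # zero-SE configuration collapses every draw onto the means
  frozen <- cfg
  frozen$parameters$se[frozen$parameters$family != "fixed"] <- 0
  d0 <- sample_parameters(frozen, n = 3, seed = 1)
  for (nm in frozen$parameters$name) {
    expect_equal(d0[[nm]],
                 rep(frozen$parameters$mean[frozen$parameters$name == nm], 3))
  }
  # large-sample mean of an uncertain cost hits its printed mean
  big <- sample_parameters(cfg, n = 1e5, seed = 7)
  expect_lt(abs(mean(big$cost_bsc_month) - 489) / 489, 0.01)
})

test_that("configuration loading validates schema and applies defaults", {
  path <- system.file("extdata", "imbrave_th_2023.yaml", package = "hccmarkov")
  cfg <- load_config(path)
  expect_s3_class(cfg, "hcc_config")
  expect_equal(cfg$parameters$mean[cfg$parameters$name == "hr_os"], 0.40)
  expect_equal(cfg$settings$psa_iterations, 5000)
  expect_equal(cfg$budget$patients_per_year, c(224, 324, 425, 525, 625))

  # omitted optional settings fall back to documented defaults
  tmp <- withr::local_tempfile(fileext = ".yaml")
  raw <- yaml::read_yaml(path)
  raw$settings$psa_seed <- NULL
  yaml::write_yaml(raw, tmp)
  expect_equal(load_config(tmp)$settings$psa_seed, 1234)

  # a missing mandatory parameter is named in the error
  raw2 <- yaml::read_yaml(path)
  raw2$parameters <- purrr::discard(raw2$parameters, ~ .x$name == "hr_os")
  yaml::write_yaml(raw2, tmp)
  expect_error(load_config(tmp), "hr_os")

  # invariant violations are rejected
  raw3 <- yaml::read_yaml(path)
  idx <- which(purrr::map_chr(raw3$parameters, "name") == "u_progression_free")
  raw3$parameters[[idx]]$mean <- 1.2
  yaml::write_yaml(raw3, tmp)
  expect_error(load_config(tmp), "beta")

  expect_error(load_config("/nonexistent/file.yaml"), "not found")

  # round trip through write_config
  tmp2 <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, tmp2)
  again <- load_config(tmp2)
  expect_equal(again$parameters, cfg$parameters)
  expect_equal(again$settings, cfg$settings)
})

test_that("config invariants are enforced", {
  expect_error(default_config(settings = list(discount_rate_annual = -0.01)),
               "discount_rate_annual")
  expect_error(default_config(settings = list(horizon_cycles = 0)),
               "horizon_cycles")
  expect_error(default_config(settings = list(wtp_thresholds = c(0, 100))),
               "wtp_thresholds")
  expect_error(default_config(settings = list(monitoring = list(labs = 0, ct = 2, chest = 3))),
               "monitoring")
  expect_error(default_config(budget = list(initial_access = 0.9)),
               "access")
})
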