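test_that("transition schedules follow the piecewise base case and HR adjustment", {
  cfg <- test_config()
  bsc <- build_schedule(cfg, "BSC")
  expect_equal(bsc$p_progress[3], 0.29)
  expect_equal(bsc$p_death_disease[3], 0.17)
  expect_equal(bsc$p_progress[6], 0.29)
  expect_equal(bsc$p_progress[7], 0.24)
  expect_equal(bsc$p_death_disease[12], 0.17)
  expect_equal(bsc$p_death_disease[13], 0.10)

  ab <- build_schedule(cfg, "A+B")
  expect_equal(ab$p_death_disease[3], 1 - 0.83^0.4, tolerance = 1e-12)
  expect_equal(ab$p_death_disease[3], 0.07182, tolerance = 1e-4)
  expect_equal(ab$p_progress[3], 1 - 0.71^0.34, tolerance = 1e-12)

  # unit hazard ratios collapse the treated arm onto the comparator
  neutral <- build_schedule(cfg, "A+B", draw = list(hr_pfs = 1, hr_os = 1))
  expect_equal(neutral$p_progress, bsc$p_progress)
  expect_equal(neutral$p_death_disease, bsc$p_death_disease)

  expect_error(build_schedule(cfg, "XYZ"))
})

test_that("the cohort trace conserves occupancy and absorbs into death", {
  cfg <- test_config()
  lt <- test_lt()
  for (arm in c("BSC", "A+B")) {
    tr <- run_trace(build_schedule(cfg, arm), lt, cfg)
    expect_equal(tr$progression_free + tr$progression + tr$dead,
                 rep(1, nrow(tr)), tolerance = 1e-12)
    expect_true(all(diff(tr$dead) >= -1e-15))
    expect_true(all(tr$progression_free >= 0 & tr$progression >= 0))
    expect_equal(unlist(tr[1, c("progression_free", "progression", "dead")]),
                 c(progression_free = 1, progression = 0, dead = 0))
  }
})

test_that("survival against the closed-form geometric benchmark", {
  cfg <- test_config()
  tr <- run_trace(build_schedule(cfg, "BSC"), test_lt(), cfg)
  # same monthly death probability from both alive states, so the alive
  # fraction is a pure geometric decay; background mortality perturbs it
  # by well under 0.002 at these rates
  expect_lt(abs(tr$alive[tr$cycle == 4] - 0.83^4), 0.002)
  expect_lt(abs(tr$alive[tr$cycle == 12] - 0.83^12), 0.002)
  nobg <- run_trace(build_schedule(cfg, "BSC"), zero_lt(), cfg)
  expect_equal(nobg$alive[nobg$cycle == 12], 0.83^12, tolerance = 1e-12)
})

test_that("median survival reproduces the validated 4 and 10 months", {
  cfg <- test_config()
  lt <- test_lt()
  expect_identical(median_survival(run_trace(build_schedule(cfg, "BSC"), lt, cfg)), 4L)
  expect_identical(median_survival(run_trace(build_schedule(cfg, "A+B"), lt, cfg)), 10L)

  # immediate-death schedule kills the cohort in one cycle
  lethal <- build_schedule(cfg, "BSC")
  lethal$p_progress[] <- 0
  lethal$p_death_disease[] <- 1 - 1e-15
  tr <- run_trace(lethal, zero_lt(), cfg)
  expect_identical(median_survival(tr), 1L)
  expect_lt(tr$alive[tr$cycle == 1], 1e-9)

  # an (almost) immortal cohort never reaches the median
  idle <- build_schedule(cfg, "BSC")
  idle$p_progress[] <- 0
  idle$p_death_disease[] <- 0
  tr0 <- run_trace(idle, zero_lt(), cfg)
  expect_equal(tr0$progression_free, rep(1, nrow(tr0)))
  expect_warning(m <- median_survival(tr0), "not reached")
  expect_true(is.na(m))
})

test_that("infeasible schedules are rejected with a cycle diagnostic", {
  cfg <- test_config()
  bad <- build_schedule(cfg, "BSC")
  bad$p_progress[5] <- 0.95
  expect_error(run_trace(bad, test_lt(), cfg), "cycle 5")
})

test_that("state occupancy time partitions into PF plus progression", {
  cfg <- test_config()
  tr <- run_trace(build_schedule(cfg, "BSC"), test_lt(), cfg)
  expect_equal(
    state_time(tr, "alive"),
    state_time(tr, "progression_free") + state_time(tr, "progression"),
    tolerance = 1e-12
  )
  # geometric closed form on the piecewise schedule, no background:
  # sum_{c=1}^{12} 0.83^c + 0.83^12 * sum_{k>=1} 0.9^k
  tr0 <- run_trace(build_schedule(cfg, "BSC"), zero_lt(), cfg)
  closed <- 0.83 * (1 - 0.83^12) / 0.17 + 0.83^12 * 0.9 / 0.1
  expect_equal(state_time(tr0, "alive"), closed, tolerance = 1e-7)
  expect_equal(state_time(tr0, "alive"), 5.3, tolerance = 0.01)
  expect_lte(state_time(tr0, "alive", discounted = TRUE, rate = 0.03),
             state_time(tr0, "alive"))
  # dead-state time of an immortal cohort is zero
  expect_equal(state_time(immortal_pf_trace(24), "dead"), 0)
})

test_that("lower OS hazard ratios never reduce survival", {
  cfg <- test_config()
  lt <- test_lt()
  hrs <- c(0.8, 0.6, 0.4, 0.2)
  alive <- lapply(hrs, function(h) {
    tr <- run_trace(build_schedule(cfg, "A+B", draw = list(hr_os = h)), lt, cfg)
    tr$alive[tr$cycle %in% 1:24]
  })
  for (i in seq_len(length(hrs) - 1)) {
    expect_true(all(alive[[i + 1]] >= alive[[i]] - 1e-12))
  }
})
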