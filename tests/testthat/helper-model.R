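# Shared fixtures.  Everything is built in code; the expensive objects
# (life table, full-size PSA) are computed once per test run and cached.

.cache <- new.env(parent = emptyenv())

test_config <- function() {
  if (is.null(.cache$config)) .cache$config <- default_config()
  .cache$config
}

test_lt <- function() {
  if (is.null(.cache$lt)) .cache$lt <- make_life_table()
  .cache$lt
}

# Life table with no background mortality at any age.
zero_lt <- function() {
  tibble::tibble(age = 0:110, annual_mortality = 0)
}

# Full-size probabilistic run at the configured defaults, shared by the
# acceptance checks.
full_psa <- function() {
  if (is.null(.cache$psa)) {
    .cache$psa <- run_psa(test_config(), test_lt())
  }
  .cache$psa
}

# A minimal hand-built trace: the whole cohort sits progression-free for
# `cycles` cycles.
immortal_pf_trace <- function(cycles) {
  tr <- tibble::tibble(
    cycle = 0:cycles,
    age = 50 + (0:cycles) / 12,
    progression_free = 1,
    progression = 0,
    dead = 0,
    new_deaths = 0,
    alive = 1
  )
  class(tr) <- c("hcc_trace", class(tr))
  attr(tr, "arm") <- "A+B"
  tr
}
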