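#' Build a synthetic age-specific life table
#'
#' Generates a Gompertz-shaped annual mortality schedule,
#' `q(a) = min(q50 * 2^((a - 50) / doubling_years), 0.99)`, tabulated per
#' single year of age.  This is a deliberately synthetic stand-in for a
#' national general-population life table: it reproduces the order of
#' magnitude and age-doubling behaviour of adult all-cause mortality
#' without claiming to match any published table.  Model results are
#' insensitive to it because disease-specific mortality dominates at every
#' cycle (a property the test suite checks).
#'
#' @param q50 Annual probability of death at age 50 (default 0.005).
#' @param doubling_years Years over which mortality doubles (default 8).
#' @param max_age Last tabulated age (default 110; must be >= 100).
#' @return A tibble of class `hcc_life_table` with columns `age`
#'   (band start, years) and `annual_mortality`.
#' @examples
#' lt <- make_life_table()
#' lt[lt$age %in% c(50, 58), ]   # one doubling apart
#' @export
make_life_table <- function(q50 = 0.005, doubling_years = 8, max_age = 110) {
  if (q50 <= 0 || q50 >= 1) abort("`q50` must be in (0, 1).")
  if (doubling_years <= 0) abort("`doubling_years` must be positive.")
  if (max_age < 100) abort("`max_age` must cover ages up to at least 100.")
  age <- 0:max_age
  q <- pmin(q50 * 2^((age - 50) / doubling_years), 0.99)
  lt <- tibble::tibble(age = age, annual_mortality = q)
  validate_life_table(lt)
}

validate_life_table <- function(lt) {
  if (!all(c("age", "annual_mortality") %in% names(lt))) {
    abort("a life table needs columns `age` and `annual_mortality`.")
  }
  if (is.unsorted(lt$age, strictly = TRUE)) {
    abort("life-table ages must be strictly increasing.")
  }
  if (any(lt$annual_mortality < 0 | lt$annual_mortality >= 1)) {
    abort("annual mortality probabilities must lie in [0, 1).")
  }
  if (min(lt$age) > 0 || max(lt$age) < 100) {
    abort("life table must cover ages 0 through 100.")
  }
  class(lt) <- c("hcc_life_table", class(tibble::tibble()))
  lt
}

#' Read / write a life table as two-column CSV
#'
#' The on-disk dialect is a plain CSV with columns `age` (band start,
#' years) and `annual_mortality` (probability).
#'
#' @param path File path.
#' @return `read_life_table()` returns a validated `hcc_life_table` tibble;
#'   `write_life_table()` returns `path` invisibly.
#' @export
read_life_table <- function(path) {
  lt <- readr::read_csv(path, col_types = readr::cols(
    age = readr::col_double(),
    annual_mortality = readr::col_double()
  ))
  attr(lt, "spec") <- NULL
  attr(lt, "problems") <- NULL
  validate_life_table(lt)
}

#' @rdname read_life_table
#' @param lt A life table.
#' @export
write_life_table <- function(lt, path) {
  lt <- validate_life_table(lt)
  readr::write_csv(lt, path)
  invisible(path)
}

#' Monthly background mortality at a given age
#'
#' Looks up the annual other-cause death probability for the age band
#' containing `age` and converts it to a one-month probability via the
#' constant-rate assumption within the year.
#'
#' @param age Age in years (may be fractional); must fall inside the
#'   table's coverage.
#' @param lt A life table from [make_life_table()] or [read_life_table()].
#' @return Monthly probability of death from other causes.  Vectorised
#'   over `age`.
#' @export
background_monthly_prob <- function(age, lt) {
  lt <- validate_life_table(lt)
  if (any(age < min(lt$age) | age >= max(lt$age) + 1)) {
    abort("`age` outside the life table's coverage.")
  }
  band <- findInterval(age, lt$age)
  q <- lt$annual_mortality[band]
  rate_to_prob(prob_to_rate(q, 1), 1 / 12)
}
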