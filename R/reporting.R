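# Writers exporting each result type in the formats downstream users
# expect (CSV for tables, JSON for summaries), plus a run manifest tying
# outputs to the configuration and seed that produced them.

.write_manifest <- function(outdir, config, seed, outputs) {
  missing <- outputs[!file.exists(file.path(outdir, outputs))]
  if (length(missing)) {
    abort(paste0("manifest lists missing output(s): ",
                 paste(missing, collapse = ", ")))
  }
  manifest <- list(
    package = "hccmarkov",
    version = as.character(utils::packageVersion("hccmarkov")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config_hash = rlang::hash(config),
    currency = "USD (2023; 34 THB/USD)",
    outputs = as.list(outputs)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Write deterministic base-case results
#'
#' Emits `base_case_arms.csv` (per-arm cost/QALY breakdown including
#' median overall survival) and `base_case_summary.json` (incrementals
#' and ICER), plus a `manifest.json`.
#'
#' @param config An `hcc_config` or path to a YAML configuration.
#' @param outdir Output directory (created if needed).
#' @param life_table Background-mortality life table.
#' @return The `hcc_cea` result, invisibly.
#' @export
report_base_case <- function(config, outdir,
                             life_table = make_life_table()) {
  config <- .as_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- run_base_case(config, life_table)
  readr::write_csv(tidy(res), file.path(outdir, "base_case_arms.csv"))
  jsonlite::write_json(as.list(glance(res)),
                       file.path(outdir, "base_case_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .write_manifest(outdir, config, NA,
                  c("base_case_arms.csv", "base_case_summary.json"))
  invisible(res)
}

#' Write probabilistic sensitivity analysis results
#'
#' Emits `psa_samples.csv` (per-iteration costs, QALYs and incrementals),
#' `ceac.csv`, and `psa_summary.json` (means and probabilistic ICER),
#' plus a `manifest.json` recording the seed.
#'
#' @inheritParams report_base_case
#' @param iterations,seed Passed to [run_psa()]; defaults from the
#'   configuration.
#' @return The `hcc_psa` result, invisibly.
#' @export
report_psa <- function(config, outdir, life_table = make_life_table(),
                       iterations = NULL, seed = NULL) {
  config <- .as_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  psa <- run_psa(config, life_table, iterations = iterations, seed = seed)
  readr::write_csv(tidy(psa), file.path(outdir, "psa_samples.csv"))
  readr::write_csv(tibble::as_tibble(ceac(psa)), file.path(outdir, "ceac.csv"))
  jsonlite::write_json(as.list(glance(psa)),
                       file.path(outdir, "psa_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .write_manifest(outdir, config, attr(psa, "seed"),
                  c("psa_samples.csv", "ceac.csv", "psa_summary.json"))
  invisible(psa)
}

#' Write one-way sensitivity (tornado) results
#'
#' Emits `tornado.csv` sorted by ICER swing, plus a `manifest.json`.
#'
#' @inheritParams report_base_case
#' @return The `hcc_tornado` tibble, invisibly.
#' @export
report_tornado <- function(config, outdir, life_table = make_life_table()) {
  config <- .as_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tor <- one_way_sa(config, life_table)
  readr::write_csv(tibble::as_tibble(tor), file.path(outdir, "tornado.csv"))
  .write_manifest(outdir, config, NA, "tornado.csv")
  invisible(tor)
}

#' Write the budget-impact projection
#'
#' Emits `budget.csv` (year, access rate, patients, undiscounted cost),
#' plus a `manifest.json`.
#'
#' @inheritParams report_base_case
#' @param mode Attribution convention, see [project_budget()].
#' @return The `hcc_budget` tibble, invisibly.
#' @export
report_budget <- function(config, outdir, life_table = make_life_table(),
                          mode = "initiation") {
  config <- .as_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  bia <- project_budget(config, life_table, mode = mode)
  readr::write_csv(tibble::as_tibble(bia), file.path(outdir, "budget.csv"))
  .write_manifest(outdir, config, NA, "budget.csv")
  invisible(bia)
}

.as_config <- function(config) {
  if (inherits(config, "hcc_config")) return(validate_config(config))
  if (is.character(config) && length(config) == 1) return(load_config(config))
  abort("`config` must be an `hcc_config` or a path to a YAML file.")
}
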