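#!/usr/bin/env Rscript
# Thin command-line wrapper over the hccmarkov reporting functions.
#   Rscript scripts/hccmarkov.R <base|psa|tornado|bia> [options]

suppressPackageStartupMessages({
  library(optparse)
  library(hccmarkov)
})

args <- commandArgs(trailingOnly = TRUE)
cmd <- if (length(args)) args[1] else ""
if (!cmd %in% c("base", "psa", "tornado", "bia")) {
  cat("usage: Rscript scripts/hccmarkov.R <base|psa|tornado|bia> [options]\n")
  quit(status = if (cmd %in% c("", "-h", "--help")) 0 else 1)
}

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character",
              default = system.file("extdata", "imbrave_th_2023.yaml",
                                    package = "hccmarkov")),
  make_option("--outdir", type = "character", default = "results"),
  make_option("--seed", type = "integer", default = NULL),
  make_option("--iterations", type = "integer", default = NULL),
  make_option("--horizon", type = "integer", default = NULL)
)), args = args[-1])

config <- load_config(opts$config)
if (!is.null(opts$horizon)) {
  config$settings$horizon_cycles <- opts$horizon
  config <- validate_config(config)
}

status <- tryCatch({
  switch(cmd,
    base = report_base_case(config, opts$outdir),
    psa = report_psa(config, opts$outdir,
                     iterations = opts$iterations, seed = opts$seed),
    tornado = report_tornado(config, opts$outdir),
    bia = report_budget(config, opts$outdir)
  )
  cat("outputs written to", opts$outdir, "\n")
  0
}, error = function(e) {
  message("error: ", conditionMessage(e))
  1
})
quit(status = status)
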