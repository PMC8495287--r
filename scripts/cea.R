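#!/usr/bin/env Rscript
# Thin command-line front end over the melcea package.
#
# Usage:
#   Rscript scripts/cea.R <subcommand> [options]
#
# Subcommands:
#   run-base       base-case ICER (icer.csv / icer_raw.csv / manifest.json)
#   one-way        one-way sensitivity for --parameter over --grid
#   threshold      ipilimumab infusion-price threshold at --wtp
#   psa            probabilistic sensitivity analysis (ceac.csv, psa_scatter.csv)
#   scenario       named scenario (--name)
#   make-fixtures  write the synthetic fixture bundle

suppressPackageStartupMessages({
  library(optparse)
  library(melcea)
})

usage_stop <- function() {
  stop("subcommand required: run-base | one-way | threshold | psa | scenario | make-fixtures",
       call. = FALSE)
}
args <- commandArgs(trailingOnly = TRUE)
if (!length(args)) usage_stop()
cmd <- args[1L]

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML parameter file (default: built-in base case)"),
  make_option("--perspective", type = "character", default = NULL,
              help = "healthcare or societal"),
  make_option("--horizon-years", type = "double", default = NULL, dest = "horizon_years"),
  make_option("--iterations", type = "integer", default = 10000L),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--wtp", type = "character", default = NULL,
              help = "comma-separated willingness-to-pay grid"),
  make_option("--parameter", type = "character", default = "cost_ipi_per_infusion"),
  make_option("--grid", type = "character", default = NULL,
              help = "comma-separated parameter values for one-way"),
  make_option("--name", type = "character", default = "base",
              help = "scenario name"),
  make_option("--out", type = "character", default = "results")
)), args = args[-1L])

cfg <- if (is.null(opts$config)) default_config() else load_config(opts$config)
if (!is.null(opts$perspective)) cfg$perspective <- opts$perspective
if (!is.null(opts$horizon_years)) cfg$horizon_years <- opts$horizon_years
num_list <- function(x) if (is.null(x)) NULL else as.numeric(strsplit(x, ",")[[1]])

log_params <- function(cfg) {
  flat <- unclass(cfg)
  flat$ci <- NULL
  message("resolved parameters:")
  for (k in sort(names(flat))) {
    message(sprintf("  %-32s %s", k, paste(format(flat[[k]]), collapse = " ")))
  }
}
log_params(cfg)

results <- list(manifest = run_manifest(cfg, seed = opts$seed,
                                        perspective = cfg$perspective,
                                        scenario = cmd))
if (cmd == "run-base") {
  results$base <- run_base_case(cfg)
  print(results$base)
} else if (cmd == "one-way") {
  grid <- num_list(opts$grid)
  if (is.null(grid)) {
    grid <- cfg[[opts$parameter]] * c(0.5, 0.75, 1, 1.25, 1.5)
  }
  ow <- one_way(opts$parameter, grid, cfg)
  results$base <- run_base_case(cfg)
  results$one_way <- cbind(parameter = opts$parameter, ow$results)
  print(ow$results)
} else if (cmd == "threshold") {
  wtp <- num_list(opts$wtp)
  thr <- threshold_ipi_price(cfg, wtp = if (length(wtp)) wtp[1] else cfg$wtp)
  cat(sprintf("threshold price $%.0f (%.0f%% below base)\n",
              thr$price, thr$pct_reduction))
  results$base <- run_base_case(cfg)
  results$one_way <- data.frame(parameter = "cost_ipi_per_infusion",
                                value = thr$price, icer_raw = thr$icer,
                                icer = round(thr$icer / 100) * 100)
} else if (cmd == "psa") {
  wtp <- num_list(opts$wtp)
  psa_args <- list(config = cfg, iterations = opts$iterations, seed = opts$seed)
  if (length(wtp)) psa_args$wtp_grid <- wtp
  results$psa <- do.call(run_psa, psa_args)
  results$base <- run_base_case(cfg)
  print(results$psa)
} else if (cmd == "scenario") {
  results$base <- scenario(opts$name, cfg)
  results$manifest$scenario <- opts$name
  print(results$base)
} else if (cmd == "make-fixtures") {
  paths <- write_fixture_bundle(opts$out, cfg, seed = opts$seed)
  message("fixture bundle written:")
  for (p in paths) message("  ", p)
  quit(save = "no", status = 0)
} else {
  usage_stop()
}

files <- write_report(results, opts$out)
message("reports written:")
for (p in files) message("  ", p)
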