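# keys every configuration must carry (CIs are optional)
required_config_keys <- function() {
  c("age_start", "horizon_years", "discount_annual", "wtp",
    "cost_ipi_per_infusion", "cost_hdi_induction", "cost_hdi_maintenance",
    "cost_infusion_ipi_induction", "cost_infusion_ipi_maintenance",
    "cost_infusion_hdi_induction", "cost_infusion_hdi_maintenance",
    "cost_toxicity_ipi", "cost_toxicity_hdi",
    "cost_stable", "cost_progressed", "cost_palliative_death",
    "soc_time_ipi_induction", "soc_time_ipi_maintenance",
    "soc_time_hdi_induction", "soc_time_hdi_maintenance",
    "soc_time_stable_off", "soc_travel_ipi_induction",
    "soc_travel_ipi_maintenance", "soc_travel_hdi_induction",
    "soc_travel_hdi_maintenance", "soc_travel_stable_off", "soc_caregiver",
    "utility_stable_on", "utility_stable_off", "utility_relapse",
    "utility_death", "disutility_tox_ipi", "disutility_tox_hdi",
    "treatment_cycles_ipi", "treatment_cycles_hdi",
    "discontinuation_ipi", "discontinuation_hdi",
    "tox_monthly_ipi", "tox_monthly_hdi",
    "hr_os_ipi", "followup_months", "surv_breakpoints",
    "os_hazards_hdi", "pfs_hazards_hdi",
    "life_base_annual_q", "life_growth", "melanoma_annual_q",
    "psa_sd_frac")
}

#' Validate a parameter configuration
#'
#' Checks key completeness and value ranges: costs non-negative, utilities
#' and probabilities in `[0, 1]`, toxicity disutility below the
#' on-treatment utility. Errors name the offending key.
#'
#' @param config named list of parameters.
#' @return The configuration, classed `melcea_config`, invisibly.
#' @export
validate_config <- function(config) {
  missing <- setdiff(required_config_keys(), names(config))
  if (length(missing)) {
    stop(sprintf("config missing key(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  for (key in grep("^(cost|soc)_", names(config), value = TRUE)) {
    if (is.numeric(config[[key]]) && any(config[[key]] < 0)) {
      stop(sprintf("config key '%s' must be non-negative", key), call. = FALSE)
    }
  }
  for (key in grep("^(utility|disutility|tox_monthly|discontinuation)",
                   names(config), value = TRUE)) {
    v <- config[[key]]
    if (any(v < 0) || any(v > 1)) {
      stop(sprintf("config key '%s' must lie in [0, 1]", key), call. = FALSE)
    }
  }
  for (key in c("disutility_tox_ipi", "disutility_tox_hdi")) {
    if (config[[key]] >= config$utility_stable_on) {
      stop(sprintf("config key '%s' must be below utility_stable_on", key),
           call. = FALSE)
    }
  }
  if (config$discount_annual < 0) {
    stop("config key 'discount_annual' must be non-negative", call. = FALSE)
  }
  if (config$hr_os_ipi <= 0) {
    stop("config key 'hr_os_ipi' must be positive", call. = FALSE)
  }
  class(config) <- unique(c("melcea_config", class(config)))
  invisible(config)
}

#' Load and validate a parameter configuration from YAML
#'
#' @param path YAML file (flat keys mirroring the published parameter
#'   table; see [default_config()]).
#' @return Validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path),
                               call. = FALSE)
  config <- yaml::read_yaml(path)
  # yaml scalars arrive as length-1; CI entries as 2-vectors already
  validate_config(config)
  config
}

#' Write a configuration to YAML
#'
#' @param config parameter configuration.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' Deterministic hash of a configuration
#'
#' MD5 of the canonical JSON serialisation; changes whenever any parameter
#' value changes.
#'
#' @param config parameter configuration.
#' @return Hex digest string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  ord <- unclass(config)
  ord <- ord[order(names(ord))]
  jsonlite::write_json(ord, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run manifest
#'
#' Provenance record attached to every results directory: configuration
#' hash, seed, perspective, horizon, scenario and package version. A
#' wall-clock timestamp is deliberately omitted so identical inputs
#' produce byte-identical reports.
#'
#' @param config parameter configuration.
#' @param seed integer seed of the run (or `NA`).
#' @param perspective,scenario labels recorded verbatim.
#' @return Named list.
#' @export
run_manifest <- function(config, seed = NA_integer_,
                         perspective = "healthcare", scenario = "base") {
  list(config_hash = config_hash(config), seed = seed,
       perspective = perspective,
       horizon_years = config$horizon_years, scenario = scenario,
       package = "melcea",
       version = as.character(utils::packageVersion("melcea")))
}

round_dollars <- function(x, to = 100) round(x / to) * to

#' Write the standard report files
#'
#' Emits `icer.csv` (rounded to the nearest $100 as reported, with full-
#' precision values in `icer_raw.csv`), and, when present in `results`,
#' `tornado.csv`, `ceac.csv`, `psa_scatter.csv`, plus `manifest.json`.
#'
#' @param results list with components `base` (a [compute_icer()] result
#'   carrying per-arm totals), optionally `one_way` (data frame), `psa`
#'   (a [run_psa()] result), and `manifest` (a [run_manifest()]).
#' @param out_dir output directory (created if missing).
#' @return Named character vector of written files, invisibly.
#' @export
write_report <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  base <- results$base
  if (!is.null(base)) {
    tab <- data.frame(
      row = c(base$ref_arm, base$new_arm, "incremental"),
      cost = c(base$cost_ref, base$cost_new, base$delta_cost),
      qaly = c(base$qaly_ref, base$qaly_new, base$delta_qaly),
      icer = c(NA, NA, base$icer_raw)
    )
    raw <- tab
    tab$cost <- round_dollars(tab$cost)
    tab$icer <- round_dollars(tab$icer)
    p <- file.path(out_dir, "icer.csv")
    utils::write.csv(format(tab, digits = 10, trim = TRUE), p,
                     row.names = FALSE, quote = FALSE, na = "")
    written <- c(written, icer = p)
    p <- file.path(out_dir, "icer_raw.csv")
    utils::write.csv(format(raw, digits = 15, trim = TRUE), p,
                     row.names = FALSE, quote = FALSE, na = "")
    written <- c(written, icer_raw = p)
  }
  if (!is.null(results$one_way)) {
    p <- file.path(out_dir, "tornado.csv")
    utils::write.csv(format(results$one_way, digits = 12, trim = TRUE), p,
                     row.names = FALSE, quote = FALSE, na = "")
    written <- c(written, tornado = p)
  }
  if (!is.null(results$psa)) {
    p <- file.path(out_dir, "ceac.csv")
    utils::write.csv(format(results$psa$ceac, digits = 12, trim = TRUE), p,
                     row.names = FALSE, quote = FALSE)
    written <- c(written, ceac = p)
    p <- file.path(out_dir, "psa_scatter.csv")
    scatter <- data.frame(iteration = seq_along(results$psa$delta_cost),
                          delta_cost = results$psa$delta_cost,
                          delta_qaly = results$psa$delta_qaly)
    utils::write.csv(format(scatter, digits = 12, trim = TRUE), p,
                     row.names = FALSE, quote = FALSE)
    written <- c(written, psa_scatter = p)
  }
  manifest <- results$manifest
  if (is.null(manifest)) manifest <- list(package = "melcea")
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  written <- c(written, manifest = p)
  invisible(written)
}
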