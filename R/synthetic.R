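#' Piecewise-exponential survival curve specification
#'
#' Emulates trial-like OS/PFS target curves as piecewise-exponential
#' survival on a monthly grid, optionally linked to a reference arm through
#' a proportional-hazards ratio (the linked arm then satisfies
#' `S_linked(m) = S_ref(m)^hr` exactly).
#'
#' @param arm arm label.
#' @param breakpoints interior interval boundaries in months (increasing).
#' @param os_hazards,pfs_hazards monthly hazards per interval
#'   (`length(breakpoints) + 1` each); PFS hazards must be at least the OS
#'   hazards so that PFS stays below OS.
#' @param hr optional proportional-hazards multiplier applied to both
#'   hazard sets (e.g. 0.78 for the ipilimumab arm linked to HDI).
#' @return Object of class `piecewise_exp_spec`.
#' @export
piecewise_exp_spec <- function(arm, breakpoints, os_hazards, pfs_hazards,
                               hr = 1) {
  stopifnot(length(os_hazards) == length(breakpoints) + 1L,
            length(pfs_hazards) == length(os_hazards))
  if (any(os_hazards < 0) || any(pfs_hazards < 0) || hr < 0) {
    stop("hazards and hazard ratios must be non-negative", call. = FALSE)
  }
  if (any(pfs_hazards < os_hazards)) {
    stop("PFS hazards must be >= OS hazards (PFS <= OS)", call. = FALSE)
  }
  if (is.unsorted(breakpoints, strictly = TRUE)) {
    stop("breakpoints must be strictly increasing", call. = FALSE)
  }
  structure(list(arm = arm, breakpoints = breakpoints,
                 os_hazards = os_hazards * hr, pfs_hazards = pfs_hazards * hr,
                 hr = hr),
            class = "piecewise_exp_spec")
}

# cumulative hazard at integer months 0..months for a piecewise-constant
# monthly hazard
cumulative_hazard <- function(breakpoints, hazards, months) {
  h_per_month <- hazards[findInterval(0:(months - 1), breakpoints) + 1L]
  c(0, cumsum(h_per_month))
}

#' Generate monthly OS/PFS target curves
#'
#' @param spec a [piecewise_exp_spec()].
#' @param months last month of the grid (trial follow-up, typically 78).
#' @return A [survival_targets()] data frame for months `0..months`.
#' @export
generate_targets <- function(spec, months = 78) {
  stopifnot(inherits(spec, "piecewise_exp_spec"), months >= 1)
  H_os <- cumulative_hazard(spec$breakpoints, spec$os_hazards, months)
  H_pfs <- cumulative_hazard(spec$breakpoints, spec$pfs_hazards, months)
  survival_targets(data.frame(month = 0:months,
                              os = exp(-H_os), pfs = exp(-H_pfs)))
}

#' Generate a synthetic background/melanoma life table
#'
#' Background annual all-cause mortality grows geometrically with age
#' (a Gompertz-like fixture standing in for population life tables); the
#' melanoma-specific column is constant and applies to relapsed patients
#' under registry extrapolation.
#'
#' @param start_age first tabulated age.
#' @param horizon_years years of coverage beyond `start_age`.
#' @param base_annual_q annual all-cause death probability at `start_age`.
#' @param growth per-year multiplier on the annual probability (>= 1
#'   expected; a warning is issued otherwise).
#' @param melanoma_annual_q constant annual melanoma-specific death
#'   probability applied to survivors beyond trial follow-up under
#'   registry extrapolation.
#' @return A [life_table()].
#' @export
generate_life_table <- function(start_age = 54, horizon_years = 50,
                                base_annual_q = 0.005, growth = 1.09,
                                melanoma_annual_q = 0.04) {
  if (base_annual_q < 0 || base_annual_q >= 1 ||
      melanoma_annual_q < 0 || melanoma_annual_q >= 1) {
    stop("annual probabilities must lie in [0, 1)", call. = FALSE)
  }
  if (growth < 1) warning("mortality usually grows with age; growth < 1 supplied")
  age <- start_age:(start_age + horizon_years)
  q <- pmin(1, base_annual_q * growth^(age - start_age))
  life_table(age, q, melanoma_annual_q)
}

#' Base-case parameter configuration
#'
#' All monetary values are 2020 USD and all utility values are annual, as
#' published; 95% confidence intervals feed the probabilistic sensitivity
#' analysis (standard deviation = CI half-width / 1.96; parameters without
#' a CI default to `psa_sd_frac` of the mean). The synthetic survival
#' section defines the piecewise-exponential emulation of the E1609-like
#' target curves (HDI reference hazards plus a proportional-hazards ratio
#' of 0.78 for ipilimumab) — these hazards, the per-cycle toxicity
#' probabilities, the life-table fixture and the hazard-ratio CI are
#' synthetic stand-ins, not published values.
#'
#' @return Named list of parameters (class `melcea_config`).
#' @export
default_config <- function() {
  config <- list(
    # cohort
    age_start = 54,
    horizon_years = 10,
    discount_annual = 0.03,
    wtp = 100000,
    perspective = "healthcare",
    extrapolation = "registry",
    # drug costs (per cycle / per infusion)
    cost_ipi_per_infusion = 54850,
    cost_hdi_induction = 26750,
    cost_hdi_maintenance = 7782,
    # infusion costs (per cycle)
    cost_infusion_ipi_induction = 196,
    cost_infusion_ipi_maintenance = 49,
    cost_infusion_hdi_induction = 2954,
    cost_infusion_hdi_maintenance = 1772,
    # drug toxicity costs (per toxic cycle)
    cost_toxicity_ipi = 7975,
    cost_toxicity_hdi = 1625,
    # disease costs (per cycle) and one-time palliative cost
    cost_stable = 1066,
    cost_progressed = 11365,
    cost_palliative_death = 22731,
    stable_cost_on_treatment = TRUE,
    # societal add-ons (per cycle)
    soc_time_ipi_induction = 204,
    soc_time_ipi_maintenance = 51,
    soc_time_hdi_induction = 3062,
    soc_time_hdi_maintenance = 1837,
    soc_time_stable_off = 153,
    soc_travel_ipi_induction = 65,
    soc_travel_ipi_maintenance = 16,
    soc_travel_hdi_induction = 980,
    soc_travel_hdi_maintenance = 588,
    soc_travel_stable_off = 49,
    soc_caregiver = 619,
    # health utilities (annual) and toxicity disutility tolls
    utility_stable_on = 0.83,
    utility_stable_off = 0.96,
    utility_relapse = 0.52,
    utility_death = 0,
    disutility_tox_ipi = 0.0134,
    disutility_tox_hdi = 0.0126,
    # treatment course
    treatment_cycles_ipi = 14,
    treatment_cycles_hdi = 12,
    discontinuation_ipi = 0.391,
    discontinuation_hdi = 0,
    weight_kg = 84.2,
    bsa_m2 = 1.79,
    # synthetic per-cycle grade 3-5 toxicity probabilities (chosen so the
    # cumulative on-treatment incidence is trial-scale: ~37% ipilimumab,
    # ~79% HDI)
    tox_monthly_ipi = 0.0304,
    tox_monthly_hdi = 0.1222,
    # synthetic E1609-like survival emulation
    hr_os_ipi = 0.78,
    hr_ci = c(0.61, 0.99),  # synthetic placeholder CI for the PSA lognormal
    followup_months = 78,
    surv_breakpoints = 24,
    os_hazards_hdi = c(0.007, 0.004),
    pfs_hazards_hdi = c(0.022, 0.008),
    # synthetic life-table fixture
    life_base_annual_q = 0.005,
    life_growth = 1.09,
    melanoma_annual_q = 0.04,
    # PSA
    psa_sd_frac = 0.20,
    psa_iterations = 100000
  )
  config$ci <- list(
    cost_ipi_per_infusion = c(33349, 76351),
    cost_hdi_induction = c(16264, 37236),
    cost_hdi_maintenance = c(4731, 10833),
    cost_infusion_ipi_induction = c(119, 273),
    cost_infusion_ipi_maintenance = c(30, 68),
    cost_infusion_hdi_induction = c(1796, 4112),
    cost_infusion_hdi_maintenance = c(1077, 2467),
    cost_toxicity_ipi = c(4849, 11101),
    cost_toxicity_hdi = c(988, 2262),
    cost_stable = c(571, 1307),
    cost_progressed = c(6910, 15820),
    cost_palliative_death = c(13820, 31642),
    soc_time_ipi_induction = c(124, 284),
    soc_time_ipi_maintenance = c(31, 71),
    soc_time_hdi_induction = c(1862, 4262),
    soc_time_hdi_maintenance = c(1117, 2557),
    soc_time_stable_off = c(93, 213),
    soc_travel_ipi_induction = c(40, 90),
    soc_travel_ipi_maintenance = c(10, 22),
    soc_travel_hdi_induction = c(596, 1364),
    soc_travel_hdi_maintenance = c(358, 818),
    soc_travel_stable_off = c(30, 68),
    soc_caregiver = c(401, 882),
    utility_stable_on = c(0.50, 1.00),
    utility_stable_off = c(0.58, 1.00),
    utility_relapse = c(0.44, 0.61),
    disutility_tox_ipi = c(0.0081, 0.0187),
    disutility_tox_hdi = c(0.0076, 0.0175)
  )
  class(config) <- c("melcea_config", "list")
  config
}

#' Write the complete fixture bundle
#'
#' Emits everything the pipeline consumes — both arms' survival-target
#' CSVs, the life-table CSV, the parameter configuration (YAML) and a JSON
#' manifest with the seed and the configuration hash — so the whole
#' analysis is regenerable without downloads. Generation is deterministic:
#' the same seed and configuration produce byte-identical files.
#'
#' @param dir output directory (created if missing).
#' @param config parameter configuration, default [default_config()].
#' @param seed integer recorded in the manifest.
#' @return Named character vector of written paths, invisibly.
#' @export
write_fixture_bundle <- function(dir, config = default_config(), seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  months <- config$followup_months
  paths <- c(
    targets_hdi = file.path(dir, "targets_hdi.csv"),
    targets_ipilimumab = file.path(dir, "targets_ipilimumab.csv"),
    life_table = file.path(dir, "life_table_synthetic.csv"),
    config = file.path(dir, "config.yaml"),
    manifest = file.path(dir, "manifest.json")
  )
  for (arm in c("hdi", "ipilimumab")) {
    tg <- generate_targets(arm_survival_spec(arm, config), months)
    utils::write.csv(format(as.data.frame(tg), digits = 15, trim = TRUE),
                     paths[[paste0("targets_", arm)]],
                     row.names = FALSE, quote = FALSE)
  }
  life <- config_life_table(config)
  utils::write.csv(format(as.data.frame(life), digits = 15, trim = TRUE),
                   paths[["life_table"]], row.names = FALSE, quote = FALSE)
  write_config(config, paths[["config"]])
  manifest <- list(seed = as.integer(seed), config_hash = config_hash(config),
                   package = "melcea",
                   version = as.character(utils::packageVersion("melcea")))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}

#' Survival-curve specification for one arm from the configuration
#'
#' @param arm `"hdi"` (reference) or `"ipilimumab"` (proportional-hazards
#'   linked with `config$hr_os_ipi`).
#' @param config parameter configuration.
#' @param hr override for the ipilimumab hazard ratio (sensitivity/PSA).
#' @return A [piecewise_exp_spec()].
#' @export
arm_survival_spec <- function(arm, config, hr = NULL) {
  link <- if (arm == "ipilimumab") {
    if (is.null(hr)) config$hr_os_ipi else hr
  } else 1
  piecewise_exp_spec(arm, config$surv_breakpoints,
                     config$os_hazards_hdi, config$pfs_hazards_hdi,
                     hr = link)
}

#' Life table implied by the configuration's fixture parameters
#'
#' @param config parameter configuration.
#' @param horizon_years coverage beyond the starting age (defaults to the
#'   longest supported horizon).
#' @return A [life_table()].
#' @export
config_life_table <- function(config, horizon_years = 50) {
  generate_life_table(config$age_start, horizon_years,
                      config$life_base_annual_q, config$life_growth,
                      config$melanoma_annual_q)
}
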