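#' Run the full pipeline for one arm
#'
#' Generates the arm's survival targets from the configuration, calibrates
#' the monthly transition schedule, runs the cohort and accumulates
#' discounted cost and QALY totals.
#'
#' @param arm `"hdi"` or `"ipilimumab"`.
#' @param config parameter configuration (see [default_config()]).
#' @param perspective `"healthcare"` or `"societal"` (defaults to the
#'   configuration's).
#' @param hr override of the ipilimumab hazard ratio.
#' @return List with `cost`, `qaly`, `trace`, `schedule`, `arm_econ`.
#' @export
run_arm <- function(arm, config, perspective = NULL, hr = NULL) {
  if (is.null(perspective)) perspective <- config$perspective
  horizon <- horizon_config(config$horizon_years, config$discount_annual)
  targets <- generate_targets(arm_survival_spec(arm, config, hr = hr),
                              months = config$followup_months)
  econ <- arm_economics(arm, config)
  life <- config_life_table(config,
                            horizon_years = ceiling(config$horizon_years) + 1)
  schedule <- calibrate_schedule(targets, econ$course, life,
                                 mode = config$extrapolation,
                                 horizon = horizon,
                                 start_age = config$age_start)
  trace <- run_cohort(schedule, "stable_on", horizon)
  totals <- accumulate(trace, econ, horizon, perspective)
  list(arm = arm, cost = totals$cost, qaly = totals$qaly,
       exposures = totals$exposures, trace = trace, schedule = schedule,
       arm_econ = econ, horizon = horizon, perspective = perspective)
}

#' Incremental cost-effectiveness ratio
#'
#' `delta_cost / delta_qaly` of the new strategy against the reference,
#' with the reported ICER rounded to the nearest $100. When the new
#' strategy is cheaper and more effective (or dearer and less effective) a
#' dominance flag is set instead of an ICER; a zero QALY difference leaves
#' the ICER undefined (flagged, not an error).
#'
#' @param cost_ref,qaly_ref discounted totals of the reference arm.
#' @param cost_new,qaly_new discounted totals of the comparator arm.
#' @param ref_arm,new_arm labels used in reports.
#' @return Object of class `cea_result`.
#' @export
compute_icer <- function(cost_ref, qaly_ref, cost_new, qaly_new,
                         ref_arm = "hdi", new_arm = "ipilimumab") {
  stopifnot(is.finite(cost_ref), is.finite(qaly_ref),
            is.finite(cost_new), is.finite(qaly_new))
  delta_cost <- cost_new - cost_ref
  delta_qaly <- qaly_new - qaly_ref
  dominance <- if (delta_cost < 0 && delta_qaly > 0) {
    "new_dominates"
  } else if (delta_cost > 0 && delta_qaly < 0) {
    "ref_dominates"
  } else NA_character_
  icer_defined <- is.na(dominance) && delta_qaly != 0
  icer_raw <- if (icer_defined) delta_cost / delta_qaly else NA_real_
  structure(list(
    ref_arm = ref_arm, new_arm = new_arm,
    cost_ref = cost_ref, qaly_ref = qaly_ref,
    cost_new = cost_new, qaly_new = qaly_new,
    delta_cost = delta_cost, delta_qaly = delta_qaly,
    icer_raw = icer_raw, icer = round_dollars(icer_raw),
    icer_defined = icer_defined, dominance = dominance
  ), class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("<cea_result> %s vs %s\n", x$new_arm, x$ref_arm))
  cat(sprintf("  %-12s cost $%s  qaly %.4f\n", x$ref_arm,
              format(round(x$cost_ref), big.mark = ","), x$qaly_ref))
  cat(sprintf("  %-12s cost $%s  qaly %.4f\n", x$new_arm,
              format(round(x$cost_new), big.mark = ","), x$qaly_new))
  cat(sprintf("  incremental  cost $%s  qaly %.4f\n",
              format(round(x$delta_cost), big.mark = ","), x$delta_qaly))
  if (!is.na(x$dominance)) {
    cat(sprintf("  dominance: %s\n", x$dominance))
  } else if (x$icer_defined) {
    cat(sprintf("  ICER $%s/QALY (rounded to nearest $100)\n",
                format(x$icer, big.mark = ",")))
  } else {
    cat("  ICER undefined (zero QALY difference)\n")
  }
  invisible(x)
}

#' Base-case comparison of ipilimumab versus HDI
#'
#' @param config parameter configuration.
#' @param perspective `"healthcare"` or `"societal"`.
#' @return A [compute_icer()] result.
#' @export
run_base_case <- function(config = default_config(), perspective = NULL) {
  validate_config(config)
  ref <- run_arm("hdi", config, perspective)
  new <- run_arm("ipilimumab", config, perspective)
  compute_icer(ref$cost, ref$qaly, new$cost, new$qaly)
}

#' Net monetary benefit
#'
#' `wtp * qaly - cost`; at a given willingness-to-pay the strategy with the
#' larger net monetary benefit is the cost-effective one.
#'
#' @param cost,qaly discounted totals.
#' @param wtp willingness-to-pay threshold (USD/QALY, positive).
#' @export
net_monetary_benefit <- function(cost, qaly, wtp) {
  if (any(wtp <= 0)) stop("`wtp` must be positive", call. = FALSE)
  wtp * qaly - cost
}

#' One-way sensitivity analysis for a single parameter
#'
#' Re-runs the full pipeline (recalibration included) at each grid value,
#' holding every other parameter at its base-case value, and reports the
#' ICER curve plus the willingness-to-pay crossing (linear interpolation
#' between the bracketing grid points) if the curve crosses it.
#'
#' @param parameter configuration key to vary.
#' @param grid parameter values to evaluate.
#' @param config base configuration.
#' @param wtp willingness-to-pay threshold used to locate the crossing.
#' @param perspective cost perspective.
#' @return Object of class `one_way_result`: data frame `results`
#'   (`value`, `icer_raw`, `icer`) plus `threshold_value` (or `NA`).
#' @export
one_way <- function(parameter, grid, config = default_config(),
                    wtp = config$wtp, perspective = NULL) {
  if (!parameter %in% names(config)) {
    stop(sprintf("unknown parameter '%s'", parameter), call. = FALSE)
  }
  if (!length(grid)) stop("`grid` must be non-empty", call. = FALSE)
  icer_raw <- vapply(grid, function(v) {
    cfg <- config
    cfg[[parameter]] <- v
    run_base_case(cfg, perspective)$icer_raw
  }, numeric(1))
  threshold_value <- NA_real_
  s <- sign(icer_raw - wtp)
  cross <- which(diff(s) != 0 & is.finite(diff(s)))
  if (length(cross)) {
    i <- cross[1L]
    threshold_value <- grid[i] + (wtp - icer_raw[i]) *
      (grid[i + 1L] - grid[i]) / (icer_raw[i + 1L] - icer_raw[i])
  }
  structure(list(parameter = parameter,
                 results = data.frame(value = grid, icer_raw = icer_raw,
                                      icer = round_dollars(icer_raw)),
                 wtp = wtp, threshold_value = threshold_value),
            class = "one_way_result")
}

#' Threshold price by bisection
#'
#' Finds the value at which the model's ICER equals the willingness-to-pay
#' threshold, bisecting until `|ICER - wtp| <= tol` (default $1). The
#' bracket must straddle the threshold.
#'
#' @param wtp willingness-to-pay threshold (USD/QALY).
#' @param model function mapping a price to a raw ICER (see
#'   [ipi_price_model()] for the standard closure over the pipeline).
#' @param bracket length-2 numeric price interval.
#' @param tol ICER tolerance in USD/QALY.
#' @return List with `price`, `icer` and the iteration count.
#' @export
threshold_price <- function(wtp, model, bracket, tol = 1) {
  lo <- min(bracket); hi <- max(bracket)
  f_lo <- model(lo) - wtp; f_hi <- model(hi) - wtp
  if (!is.finite(f_lo) || !is.finite(f_hi) || sign(f_lo) == sign(f_hi)) {
    stop("ICER at the bracket endpoints does not straddle the threshold",
         call. = FALSE)
  }
  iter <- 0L
  repeat {
    iter <- iter + 1L
    mid <- (lo + hi) / 2
    f_mid <- model(mid) - wtp
    if (abs(f_mid) <= tol || (hi - lo) < 1e-9 * max(1, abs(hi)) || iter > 200L) {
      return(list(price = mid, icer = f_mid + wtp, iterations = iter))
    }
    if (sign(f_mid) == sign(f_lo)) {
      lo <- mid; f_lo <- f_mid
    } else {
      hi <- mid
    }
  }
}

#' Pipeline closure over the ipilimumab per-infusion price
#'
#' @param config base configuration.
#' @param perspective cost perspective.
#' @return Function mapping a per-infusion price (USD) to the raw ICER.
#' @export
ipi_price_model <- function(config = default_config(), perspective = NULL) {
  force(config); force(perspective)
  function(price) {
    cfg <- config
    cfg$cost_ipi_per_infusion <- price
    res <- run_base_case(cfg, perspective)
    # return the raw ratio even when the new arm dominates (negative
    # ratio), so a bracket can straddle any positive threshold
    res$delta_cost / res$delta_qaly
  }
}

#' Threshold ipilimumab price and implied percent reduction
#'
#' @param config base configuration.
#' @param wtp willingness-to-pay threshold.
#' @param bracket price bracket for the bisection (defaults to 1%-100% of
#'   the base price).
#' @return List with `price`, `icer`, `pct_reduction` (percent below the
#'   base price, unrounded).
#' @export
threshold_ipi_price <- function(config = default_config(), wtp = config$wtp,
                                bracket = NULL) {
  base_price <- config$cost_ipi_per_infusion
  if (is.null(bracket)) bracket <- c(0.01, 1) * base_price
  hit <- threshold_price(wtp, ipi_price_model(config), bracket)
  hit$pct_reduction <- percent_reduction(base_price, hit$price)
  hit
}

#' Percent reduction between two prices
#'
#' @param base,new base and reduced price.
#' @return Unrounded percent reduction, `100 * (1 - new / base)`.
#' @export
percent_reduction <- function(base, new) 100 * (1 - new / base)

#' Named scenario analyses
#'
#' Predefined configurations reported alongside the base case:
#' `cure_extrapolation` (patients alive beyond trial follow-up are cured),
#' `horizon_40y` and `horizon_lifetime` (extended time horizons; lifetime
#' runs to age 100), `hr_056` (optimistic hazard ratio 0.56),
#' `discontinuation_60` (60% of ipilimumab patients stop early) and
#' `societal` (societal cost perspective). Arbitrary overrides can be
#' supplied on top; an empty override list reproduces the base case.
#'
#' @param name scenario label, or `"base"`.
#' @param config base configuration.
#' @param overrides named list of configuration overrides applied after the
#'   scenario presets.
#' @return A [compute_icer()] result.
#' @export
scenario <- function(name = "base", config = default_config(),
                     overrides = list()) {
  presets <- list(
    base = list(),
    cure_extrapolation = list(extrapolation = "cure"),
    horizon_40y = list(horizon_years = 40),
    horizon_lifetime = list(horizon_years = 100 - config$age_start),
    hr_056 = list(hr_os_ipi = 0.56),
    discontinuation_60 = list(discontinuation_ipi = 0.60),
    societal = list(perspective = "societal")
  )
  if (!name %in% names(presets)) {
    stop(sprintf("unknown scenario '%s'", name), call. = FALSE)
  }
  for (k in names(presets[[name]])) config[[k]] <- presets[[name]][[k]]
  for (k in names(overrides)) config[[k]] <- overrides[[k]]
  run_base_case(config)
}
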