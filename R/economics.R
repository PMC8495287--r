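#' Dosing schedule for one arm
#'
#' Ipilimumab 3 mg/kg: four induction infusions every 3 weeks (mapped as
#' 2, 1, 1 administrations over cycles 0-2) then one maintenance infusion
#' every 12 weeks, up to four (cycles 5, 8, 11, 14), 60-week cap. HDI: one
#' induction month (20 MU/m2 IV daily, 5 days/week, 4 weeks) then 48 weeks
#' of subcutaneous maintenance (cycles 1-12), 52-week cap; HDI drug costs
#' are per-cycle aggregates so each drug-bearing cycle counts one
#' administration unit.
#'
#' @param arm `"ipilimumab"` or `"hdi"`.
#' @return Object of class `dosing_schedule`: data frame with columns
#'   `cycle`, `administrations`, `phase` (`induction`/`maintenance`).
#' @export
build_dosing <- function(arm) {
  if (arm == "ipilimumab") {
    cycle <- 0:14
    administrations <- integer(15)
    administrations[1:3] <- c(2L, 1L, 1L)
    administrations[c(6, 9, 12, 15)] <- 1L
    phase <- c(rep("induction", 3), rep("maintenance", 12))
  } else if (arm == "hdi") {
    cycle <- 0:12
    administrations <- rep(1L, 13)
    phase <- c("induction", rep("maintenance", 12))
  } else {
    stop(sprintf("unknown arm '%s'", arm), call. = FALSE)
  }
  out <- data.frame(cycle = cycle, administrations = administrations,
                    phase = phase)
  class(out) <- c("dosing_schedule", "data.frame")
  out
}

#' Per-arm economic inputs
#'
#' Resolves the parameter configuration into per-cycle cost components for
#' one arm: per-administration drug cost, infusion administration fees,
#' societal visit costs (patient time/salary plus parking, meals and
#' travel), expected toxicity cost, and the utility/disutility inputs.
#'
#' @param arm `"ipilimumab"` or `"hdi"`.
#' @param config parameter configuration, see [default_config()].
#' @return Object of class `arm_economics`.
#' @export
arm_economics <- function(arm, config) {
  dosing <- build_dosing(arm)
  n <- nrow(dosing)
  drug <- fee <- soc_visit <- numeric(n)
  induction <- dosing$phase == "induction"
  dosed <- dosing$administrations > 0
  if (arm == "ipilimumab") {
    drug <- dosing$administrations * config$cost_ipi_per_infusion
    fee[induction & dosed] <- config$cost_infusion_ipi_induction
    fee[!induction & dosed] <- config$cost_infusion_ipi_maintenance
    soc_visit[induction & dosed] <-
      config$soc_time_ipi_induction + config$soc_travel_ipi_induction
    soc_visit[!induction & dosed] <-
      config$soc_time_ipi_maintenance + config$soc_travel_ipi_maintenance
    tox_cost <- config$cost_toxicity_ipi
    toll <- config$disutility_tox_ipi
    tox_monthly <- config$tox_monthly_ipi
    disc <- config$discontinuation_ipi
    duration <- config$treatment_cycles_ipi
  } else if (arm == "hdi") {
    drug[induction] <- config$cost_hdi_induction
    drug[!induction] <- config$cost_hdi_maintenance
    fee[induction] <- config$cost_infusion_hdi_induction
    fee[!induction] <- config$cost_infusion_hdi_maintenance
    soc_visit[induction] <-
      config$soc_time_hdi_induction + config$soc_travel_hdi_induction
    soc_visit[!induction] <-
      config$soc_time_hdi_maintenance + config$soc_travel_hdi_maintenance
    tox_cost <- config$cost_toxicity_hdi
    toll <- config$disutility_tox_hdi
    tox_monthly <- config$tox_monthly_hdi
    disc <- config$discontinuation_hdi
    duration <- config$treatment_cycles_hdi
  } else {
    stop(sprintf("unknown arm '%s'", arm), call. = FALSE)
  }
  structure(list(
    arm = arm, dosing = dosing,
    drug_cost = drug, infusion_fee = fee, soc_visit = soc_visit,
    tox_cost = tox_cost, tox_monthly = tox_monthly, toll = toll,
    course = treatment_course(arm, duration, disc, tox_monthly),
    utilities = list(stable_on = config$utility_stable_on,
                     stable_off = config$utility_stable_off,
                     relapse = config$utility_relapse,
                     death = config$utility_death),
    cost_stable = config$cost_stable,
    cost_progressed = config$cost_progressed,
    cost_palliative = config$cost_palliative_death,
    soc_off = config$soc_time_stable_off + config$soc_travel_stable_off,
    soc_caregiver = config$soc_caregiver,
    stable_cost_on_treatment = isTRUE(config$stable_cost_on_treatment)
  ), class = "arm_economics")
}

# per-cycle on-treatment administration cost components at cycle m (0-based);
# zero beyond the dosing schedule
dosing_component <- function(arm_econ, m, what) {
  v <- arm_econ[[what]]
  out <- numeric(length(m))
  idx <- m + 1L
  ok <- idx >= 1L & idx <= length(v)
  out[ok] <- v[idx[ok]]
  out
}

#' Per-member cost of occupying a state for one cycle
#'
#' Total undiscounted cost per cohort member in `state` at cycle `cycle`:
#' the on-treatment state carries drug, infusion-fee, disease-management
#' and expected toxicity costs (plus visit and caregiver costs under the
#' societal perspective); the off-treatment stable state carries the
#' disease-management cost (plus societal add-ons); relapse carries the
#' progressed-disease cost (plus caregiver); death carries no recurring
#' cost.
#'
#' @param state one of [health_states].
#' @param cycle 0-based cycle index.
#' @param arm_econ an [arm_economics()] object.
#' @param perspective `"healthcare"` (base case) or `"societal"`.
#' @export
cycle_cost <- function(state, cycle, arm_econ,
                       perspective = c("healthcare", "societal")) {
  perspective <- match.arg(perspective)
  stopifnot(state %in% health_states)
  soc <- perspective == "societal"
  stable_cost <- arm_econ$cost_stable
  caregiver <- if (soc) arm_econ$soc_caregiver else 0
  switch(state,
    stable_on = {
      on_stable <- if (arm_econ$stable_cost_on_treatment) stable_cost else 0
      dosing_component(arm_econ, cycle, "drug_cost") +
        dosing_component(arm_econ, cycle, "infusion_fee") +
        on_stable +
        arm_econ$tox_monthly * arm_econ$tox_cost +
        (if (soc) dosing_component(arm_econ, cycle, "soc_visit") else 0) +
        caregiver
    },
    stable_off = stable_cost + (if (soc) arm_econ$soc_off else 0) + caregiver,
    relapse = arm_econ$cost_progressed + caregiver,
    death = 0
  )
}

#' One-time palliative and death cost
#'
#' All patients incur the palliative-care cost in the month before death;
#' the cost attaches in full to the newly dead cohort mass of the cycle.
#'
#' @param new_death_mass fraction of the cohort dying during the cycle.
#' @param cost_palliative one-time cost (2020 USD), default from Table of
#'   parameters.
#' @export
death_transition_cost <- function(new_death_mass, cost_palliative = 22731) {
  if (any(new_death_mass < -1e-12) || any(new_death_mass > 1 + 1e-12)) {
    stop("death mass must lie in [0, 1]", call. = FALSE)
  }
  cost_palliative * new_death_mass
}

#' Per-member QALY accrued in a state over one cycle
#'
#' Annual utilities divided over 12 monthly cycles; on-treatment members
#' currently experiencing toxicity additionally lose the annualised
#' disutility toll.
#'
#' @param state one of [health_states].
#' @param on_tx_toxic_fraction fraction of on-treatment membership with an
#'   active toxicity (ignored for other states).
#' @param utilities named list with `stable_on`, `stable_off`, `relapse`,
#'   `death` annual utilities.
#' @param toll annual disutility toll for the arm's toxicity profile.
#' @export
cycle_qaly <- function(state, on_tx_toxic_fraction = 0, utilities,
                       toll = 0) {
  stopifnot(state %in% health_states)
  if (on_tx_toxic_fraction < 0 || on_tx_toxic_fraction > 1) {
    stop("toxic fraction must lie in [0, 1]", call. = FALSE)
  }
  u <- utilities[[state]] / 12
  if (state == "stable_on") u <- u - toll / 12 * on_tx_toxic_fraction
  u
}

# Discounted exposure sums shared by the deterministic accumulator and the
# vectorised PSA engine. Administration costs use start-of-cycle
# on-treatment occupancy and start-of-cycle discounting; everything
# state-attached uses half-cycle membership and midpoint discounting.
trace_exposures <- function(trace, arm_econ, horizon) {
  cycles <- trace$cycles
  df <- discount_factors(horizon)
  occ_on <- trace$occupancy[seq_len(cycles), .S_ON]
  memb <- trace$membership
  new_death <- diff(trace$occupancy[, .S_DEATH])
  drug_units <- dosing_component(arm_econ, df$cycle, "drug_cost")
  fee <- dosing_component(arm_econ, df$cycle, "infusion_fee")
  soc_visit <- dosing_component(arm_econ, df$cycle, "soc_visit")
  list(
    drug = sum(drug_units * occ_on * df$start),
    fee = sum(fee * occ_on * df$start),
    soc_visit = sum(soc_visit * occ_on * df$start),
    memb_on = sum(memb[, .S_ON] * df$midpoint),
    memb_off = sum(memb[, .S_OFF] * df$midpoint),
    memb_rel = sum(memb[, .S_REL] * df$midpoint),
    death = sum(new_death * df$start)
  )
}

#' Discounted cost and QALY totals for one arm
#'
#' Sums discounted costs and QALYs over the horizon. Administration-driven
#' costs (drug, infusion fees, societal visit costs) attach to
#' start-of-cycle on-treatment occupancy with start-of-cycle discounting;
#' state-attached costs and all QALYs attach to half-cycle membership with
#' midpoint discounting; the one-time palliative cost attaches to the newly
#' dead mass of each cycle.
#'
#' @param trace a [run_cohort()] result.
#' @param arm_econ an [arm_economics()] object for the same arm.
#' @param horizon the [horizon_config()] used for the trace.
#' @param perspective `"healthcare"` or `"societal"`.
#' @return List with `cost`, `qaly` and the underlying discounted
#'   `exposures`.
#' @export
accumulate <- function(trace, arm_econ, horizon,
                       perspective = c("healthcare", "societal")) {
  perspective <- match.arg(perspective)
  stopifnot(inherits(trace, "cohort_trace"), inherits(arm_econ, "arm_economics"))
  if (trace$cycles != horizon$cycles) {
    stop("trace and horizon cycle counts differ", call. = FALSE)
  }
  ex <- trace_exposures(trace, arm_econ, horizon)
  soc <- perspective == "societal"
  u <- arm_econ$utilities
  stable_exposure <- ex$memb_off +
    if (arm_econ$stable_cost_on_treatment) ex$memb_on else 0
  cost <- ex$drug + ex$fee +
    arm_econ$cost_stable * stable_exposure +
    arm_econ$tox_monthly * arm_econ$tox_cost * ex$memb_on +
    arm_econ$cost_progressed * ex$memb_rel +
    arm_econ$cost_palliative * ex$death
  if (soc) {
    cost <- cost + ex$soc_visit +
      arm_econ$soc_off * ex$memb_off +
      arm_econ$soc_caregiver * (ex$memb_on + ex$memb_off + ex$memb_rel)
  }
  qaly <- (u$stable_on * ex$memb_on + u$stable_off * ex$memb_off +
             u$relapse * ex$memb_rel) / 12 -
    arm_econ$toll / 12 * arm_econ$tox_monthly * ex$memb_on
  list(cost = cost, qaly = qaly, exposures = ex, perspective = perspective)
}
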