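#' Conditional per-cycle event probability from a survival curve
#'
#' Standard Kaplan-Meier decrement: the probability of the event during a
#' cycle, conditional on being event-free at its start, is
#' `1 - S_next / S_prev`.
#'
#' @param s_prev,s_next survival fractions at consecutive cycle boundaries,
#'   `0 < s_next <= s_prev <= 1`. Vectorised.
#' @return Per-cycle conditional event probability.
#' @export
monthly_event_prob <- function(s_prev, s_next) {
  if (any(s_prev <= 0)) stop("survival must be positive", call. = FALSE)
  if (any(s_next > s_prev + 1e-12)) {
    stop("survival cannot increase between cycles", call. = FALSE)
  }
  if (any(s_prev > 1 + 1e-12) || any(s_next <= 0)) {
    stop("survival fractions must lie in (0, 1]", call. = FALSE)
  }
  pmax(0, 1 - s_next / s_prev)
}

#' Convert an annual probability to a per-cycle probability
#'
#' Constant-hazard conversion: `1 - (1 - p)^(1/cycles_per_year)`.
#'
#' @param p_annual annual probability in `[0, 1]`. Vectorised.
#' @param cycles_per_year number of model cycles per year (12 for monthly).
#' @export
annual_to_cycle_prob <- function(p_annual, cycles_per_year = 12) {
  if (any(p_annual < 0) || any(p_annual > 1)) {
    stop("annual probability must lie in [0, 1]", call. = FALSE)
  }
  1 - (1 - p_annual)^(1 / cycles_per_year)
}

#' Treatment course description for one arm
#'
#' @param arm arm label.
#' @param duration_cycles maximum treatment duration in monthly cycles
#'   (ipilimumab: 14 cycles for the 60-week cap; HDI: 12 cycles for 52
#'   weeks). The forced move off treatment happens at the cycle indexed by
#'   `duration_cycles`, so drug-bearing cycles run `0..duration_cycles`.
#' @param discontinuation fraction of patients discontinuing before the
#'   treatment cap (ipilimumab base case 0.391), spread as a constant
#'   per-cycle hazard.
#' @param tox_monthly per-cycle probability of a grade 3-5 toxicity while on
#'   treatment.
#' @return Object of class `treatment_course`.
#' @export
treatment_course <- function(arm, duration_cycles, discontinuation = 0,
                             tox_monthly = 0) {
  stopifnot(length(duration_cycles) == 1L, length(discontinuation) == 1L)
  if (duration_cycles < 1) stop("`duration_cycles` must be >= 1", call. = FALSE)
  if (discontinuation < 0 || discontinuation >= 1) {
    stop("`discontinuation` must lie in [0, 1)", call. = FALSE)
  }
  if (tox_monthly < 0 || tox_monthly > 1) {
    stop("`tox_monthly` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(arm = arm, duration_cycles = as.integer(duration_cycles),
                 discontinuation = discontinuation, tox_monthly = tox_monthly),
            class = "treatment_course")
}

#' Constant per-cycle discontinuation probability
#'
#' Solves `1 - (1 - q)^duration = fraction` for the per-cycle hazard `q`
#' that spreads an overall discontinuation fraction uniformly over the
#' treatment course.
#'
#' @param course a [treatment_course()], or a numeric fraction when
#'   `duration` is supplied.
#' @param duration treatment duration in cycles (ignored when `course` is a
#'   `treatment_course`).
#' @export
discontinuation_monthly_prob <- function(course, duration = NULL) {
  if (inherits(course, "treatment_course")) {
    fraction <- course$discontinuation
    duration <- course$duration_cycles
  } else {
    fraction <- course
    if (is.null(duration)) stop("`duration` required", call. = FALSE)
  }
  if (fraction < 0 || fraction >= 1) {
    stop("discontinuation fraction must lie in [0, 1)", call. = FALSE)
  }
  1 - (1 - fraction)^(1 / duration)
}

#' Background and melanoma-specific life table
#'
#' @param age integer ages (years).
#' @param q_annual annual all-cause death probability at each age;
#'   recycled if scalar.
#' @param q_melanoma annual melanoma-specific death probability applied to
#'   survivors beyond trial follow-up under registry extrapolation;
#'   recycled if scalar.
#' @return Object of class `life_table` (a data frame).
#' @export
life_table <- function(age, q_annual, q_melanoma = 0) {
  q_annual <- rep_len(q_annual, length(age))
  if (any(q_annual < 0) || any(q_annual > 1) ||
      any(q_melanoma < 0) || any(q_melanoma > 1)) {
    stop("life-table probabilities must lie in [0, 1]", call. = FALSE)
  }
  out <- data.frame(age = as.integer(age), q_annual = q_annual,
                    q_melanoma = rep_len(q_melanoma, length(age)))
  class(out) <- c("life_table", "data.frame")
  out
}

# annual all-cause probability at a (possibly fractional) age, clamped to
# the table's range
lookup_life_table <- function(life, age, column = "q_annual") {
  idx <- pmin(pmax(floor(age) - life$age[1L] + 1, 1), nrow(life))
  life[[column]][idx]
}

#' Validate OS/PFS survival targets
#'
#' @param targets data frame with columns `month` (0-based, consecutive),
#'   `os`, `pfs`; both curves start at 1, are non-increasing, stay in
#'   `(0, 1]`, and satisfy `pfs <= os`.
#' @return The validated data frame, invisibly classed `survival_targets`.
#' @export
survival_targets <- function(targets) {
  need <- c("month", "os", "pfs")
  if (!all(need %in% names(targets))) {
    stop("targets need columns month, os, pfs", call. = FALSE)
  }
  targets <- targets[order(targets$month), need]
  if (targets$month[1L] != 0 || any(diff(targets$month) != 1)) {
    stop("target months must be consecutive starting at 0", call. = FALSE)
  }
  if (abs(targets$os[1L] - 1) > 1e-12 || abs(targets$pfs[1L] - 1) > 1e-12) {
    stop("OS and PFS targets must start at 1", call. = FALSE)
  }
  for (col in c("os", "pfs")) {
    if (any(targets[[col]] <= 0) || any(targets[[col]] > 1 + 1e-12)) {
      stop(sprintf("%s targets must lie in (0, 1]", toupper(col)), call. = FALSE)
    }
    if (any(diff(targets[[col]]) > 1e-12)) {
      stop(sprintf("%s targets must be non-increasing", toupper(col)),
           call. = FALSE)
    }
  }
  if (any(targets$pfs > targets$os + 1e-12)) {
    stop("PFS target exceeds OS target", call. = FALSE)
  }
  class(targets) <- c("survival_targets", "data.frame")
  invisible(targets)
}

# One cycle of the forward calibration decomposition. Inputs are scalars
# describing the cycle; `occ` is the current occupancy. Returns the row
# probabilities. The residual "top-up" keeps total modelled deaths equal to
# the OS decrement even while the relapse state is still (nearly) empty:
# the relapse-state death probability is capped at 1 and any remaining
# decrement is carried by the stable states, with the relapse probability
# reduced so the PFS decrement stays exact.
solve_cycle <- function(occ, e, d, b, os_next, cycle) {
  s_pf <- occ[.S_ON] + occ[.S_OFF]
  alive <- s_pf + occ[.S_REL]
  deaths_needed <- max(0, alive - os_next)
  need_rel <- deaths_needed - s_pf * b
  if (need_rel <= 0) {
    d_rel <- b                       # floor clip; slight overkill if b > 0
    b1 <- b
  } else if (need_rel <= occ[.S_REL]) {
    d_rel <- min(1, max(b, need_rel / occ[.S_REL]))
    b1 <- b
  } else {
    d_rel <- 1
    extra <- need_rel - occ[.S_REL]
    b1 <- if (s_pf > 0) b + extra / s_pf else b
    if (b1 > 1 + 1e-9) {
      stop(sprintf(
        "calibration infeasible at cycle %d: required pre-relapse death probability %.4f > 1",
        cycle, b1), call. = FALSE)
    }
    b1 <- min(1, b1)
  }
  r <- max(0, e - b1)
  list(b1 = b1, r = r, d_rel = d_rel)
}

build_row_matrix <- function(b1, r, q, forced_off, d_rel, cycle) {
  stay_on <- 1 - b1 - r - q
  if (forced_off) {
    to_off <- q + stay_on
    stay_on <- 0
  } else {
    to_off <- q
  }
  if (stay_on < -1e-12 || to_off < -1e-12) {
    stop(sprintf("calibration infeasible at cycle %d: on-treatment row overflows",
                 cycle), call. = FALSE)
  }
  stay_off <- 1 - b1 - r
  m <- matrix(0, 4L, 4L, dimnames = list(health_states, health_states))
  m[.S_ON, ] <- c(max(0, stay_on), max(0, to_off), r, b1)
  m[.S_OFF, ] <- c(0, max(0, stay_off), r, b1)
  m[.S_REL, ] <- c(0, 0, 1 - d_rel, d_rel)
  m[.S_DEATH, ] <- c(0, 0, 0, 1)
  # absorb rounding in the stay probability so rows sum to 1 exactly
  m[.S_ON, .S_ON] <- m[.S_ON, .S_ON] + (1 - sum(m[.S_ON, ]))
  if (forced_off) {
    m[.S_ON, .S_OFF] <- m[.S_ON, .S_OFF] + m[.S_ON, .S_ON]
    m[.S_ON, .S_ON] <- 0
  }
  m[.S_OFF, .S_OFF] <- m[.S_OFF, .S_OFF] + (1 - sum(m[.S_OFF, ]))
  m
}

#' Calibrate a transition schedule to survival targets
#'
#' Forward cycle-by-cycle decomposition of the target curves into monthly
#' transition probabilities. Within trial follow-up each cycle uses (i) the
#' PFS decrement as the total probability of leaving the stable states by
#' relapse or death, (ii) the background life-table probability (capped at
#' the OS decrement) as the stable-state death probability, and (iii) a
#' relapse-state death probability solved against the evolving occupancy so
#' total modelled deaths reproduce the OS decrement exactly. While the
#' relapse state is still too small to carry the required deaths, the
#' residual decrement is routed through the stable states (and the relapse
#' probability reduced accordingly) so both curves are still reproduced.
#' Treatment discontinuation moves patients from the on- to the
#' off-treatment stable state at a constant hazard, with all remaining
#' on-treatment mass forced off at the treatment cap.
#'
#' Beyond the last target month, `"registry"` extrapolation keeps the last
#' calibrated relapse probability flowing and applies the melanoma-specific
#' life-table mortality (combined with background mortality) to every
#' surviving state, while `"cure"` extrapolation treats survivors as cured:
#' background mortality only, and no further relapse.
#'
#' @param targets a [survival_targets()] data frame (month 0 up to trial
#'   follow-up, typically 78).
#' @param course a [treatment_course()].
#' @param life a [life_table()].
#' @param mode extrapolation mode, `"registry"` (base case) or `"cure"`.
#' @param horizon a [horizon_config()].
#' @param start_age cohort age at entry (years).
#' @param include_background apply background life-table mortality during
#'   trial follow-up (capped at the OS decrement). Disable to attribute all
#'   observed deaths to the trial curves alone.
#' @return A [transition_schedule()] covering `horizon$cycles` cycles.
#' @export
calibrate_schedule <- function(targets, course, life, mode = c("registry", "cure"),
                               horizon, start_age = 54,
                               include_background = TRUE) {
  mode <- match.arg(mode)
  targets <- survival_targets(as.data.frame(targets))
  stopifnot(inherits(course, "treatment_course"),
            inherits(life, "life_table"),
            inherits(horizon, "horizon_config"))
  cycles <- horizon$cycles
  followup <- min(max(targets$month), cycles)
  q_disc <- if (course$discontinuation > 0) {
    discontinuation_monthly_prob(course)
  } else 0
  dur <- course$duration_cycles

  occ <- c(1, 0, 0, 0)
  mats <- vector("list", cycles)
  r_carry <- 0
  for (m in seq_len(cycles) - 1L) {
    b_raw <- if (include_background || m >= followup) {
      annual_to_cycle_prob(lookup_life_table(life, start_age + m / 12))
    } else 0
    if (m < followup) {
      os_prev <- targets$os[m + 1L]; os_next <- targets$os[m + 2L]
      pfs_prev <- targets$pfs[m + 1L]; pfs_next <- targets$pfs[m + 2L]
      e <- monthly_event_prob(pfs_prev, pfs_next)
      d <- monthly_event_prob(os_prev, os_next)
      b <- min(b_raw, d)
      alive <- occ[.S_ON] + occ[.S_OFF] + occ[.S_REL]
      sol <- solve_cycle(occ, e, d, b, os_next = alive * os_next / os_prev,
                         cycle = m)
      r_carry <- sol$r
    } else {
      b <- b_raw
      if (mode == "registry") {
        # everyone still alive carries the melanoma-specific registry
        # mortality on top of background; relapse keeps flowing at the last
        # calibrated rate
        q_mel <- annual_to_cycle_prob(
          lookup_life_table(life, start_age + m / 12, "q_melanoma"))
        b_all <- 1 - (1 - b) * (1 - q_mel)
        sol <- list(b1 = b_all, r = r_carry, d_rel = b_all)
      } else {
        sol <- list(b1 = b, r = 0, d_rel = b)
      }
    }
    q <- if (m < dur) q_disc else 0
    mats[[m + 1L]] <- build_row_matrix(sol$b1, sol$r, q,
                                       forced_off = (m == dur),
                                       d_rel = sol$d_rel, cycle = m)
    occ <- as.vector(occ %*% mats[[m + 1L]])
  }
  sched <- transition_schedule(course$arm, mats)
  attr(sched, "followup") <- followup
  attr(sched, "mode") <- mode
  sched
}

#' Cumulative grade 3-5 toxicity incidence
#'
#' Applies the per-cycle on-treatment toxicity probability to the
#' half-cycle on-treatment membership of patients who have not yet had a
#' toxicity, giving the cumulative fraction of the cohort with at least one
#' grade 3-5 event by the end of each cycle. The curve is non-decreasing
#' and plateaus once treatment ends.
#'
#' @param course a [treatment_course()].
#' @param trace a [run_cohort()] result.
#' @return Numeric vector of length `trace$cycles` (cumulative incidence at
#'   the end of cycles `1..cycles`).
#' @export
toxicity_incidence <- function(course, trace) {
  stopifnot(inherits(course, "treatment_course"),
            inherits(trace, "cohort_trace"))
  p <- course$tox_monthly
  memb_on <- trace$membership[, .S_ON]
  cum <- numeric(trace$cycles)
  prev <- 0
  for (m in seq_len(trace$cycles)) {
    prev <- prev + p * memb_on[m] * (1 - prev)
    cum[m] <- prev
  }
  cum
}

#' Read survival targets or a life table from CSV
#'
#' @param path CSV with columns `month, os, pfs` (targets) or
#'   `age, q_annual, q_melanoma` (life table).
#' @return A [survival_targets()] data frame or a [life_table()].
#' @export
read_survival_targets <- function(path) {
  survival_targets(utils::read.csv(path))
}

#' @rdname read_survival_targets
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path)
  life_table(df$age, df$q_annual, df$q_melanoma)
}

#' Export a transition schedule to CSV
#'
#' Long format: `cycle, from_state, to_state, probability`.
#'
#' @param schedule a [transition_schedule()].
#' @param path output CSV path.
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "transition_schedule"))
  n <- length(schedule$matrices)
  out <- do.call(rbind, lapply(seq_len(n), function(i) {
    m <- schedule$matrices[[i]]
    data.frame(cycle = i - 1L,
               from_state = rep(health_states, times = 4L),
               to_state = rep(health_states, each = 4L),
               probability = as.vector(m))
  }))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
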