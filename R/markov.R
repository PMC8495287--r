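#' Health states of the cohort model
#'
#' The model follows a resected high-risk melanoma cohort through four
#' health states: stable disease on adjuvant treatment, stable disease off
#' treatment, relapsed disease, and death (absorbing). Relapse is
#' irreversible: no transition leads from the relapse state back to either
#' stable state.
#'
#' @format Character vector of the four state labels, in matrix order.
#' @export
health_states <- c("stable_on", "stable_off", "relapse", "death")

# column indices used throughout the engine
.S_ON <- 1L
.S_OFF <- 2L
.S_REL <- 3L
.S_DEATH <- 4L

#' Horizon and discounting configuration
#'
#' @param horizon_years model time horizon in years (base case 10; sensitivity
#'   analyses use up to a lifetime horizon).
#' @param discount_annual annual discount rate applied to costs and QALYs
#'   (base case 0.03).
#' @return An object of class `horizon_config` with elements `horizon_years`,
#'   `cycles` (monthly cycles, `12 * horizon_years`) and `discount_annual`.
#' @export
horizon_config <- function(horizon_years = 10, discount_annual = 0.03) {
  stopifnot(is.numeric(horizon_years), length(horizon_years) == 1L,
            is.numeric(discount_annual), length(discount_annual) == 1L)
  if (horizon_years <= 0) {
    stop("`horizon_years` must be positive", call. = FALSE)
  }
  if (discount_annual < 0) {
    stop("`discount_annual` must be non-negative", call. = FALSE)
  }
  cycles <- as.integer(round(12 * horizon_years))
  if (cycles < 1L) stop("horizon must span at least one monthly cycle", call. = FALSE)
  structure(
    list(horizon_years = horizon_years, cycles = cycles,
         discount_annual = discount_annual),
    class = "horizon_config"
  )
}

#' @export
print.horizon_config <- function(x, ...) {
  cat(sprintf("<horizon_config> %g years (%d monthly cycles), %g%% annual discount\n",
              x$horizon_years, x$cycles, 100 * x$discount_annual))
  invisible(x)
}

validate_transition_matrix <- function(m, cycle, tol = 1e-12) {
  if (!is.matrix(m) || !all(dim(m) == c(4L, 4L))) {
    stop(sprintf("cycle %d: transition matrix must be 4x4", cycle), call. = FALSE)
  }
  if (any(m < -tol) || any(m > 1 + tol)) {
    stop(sprintf("cycle %d: transition probabilities outside [0, 1]", cycle),
         call. = FALSE)
  }
  rs <- rowSums(m)
  if (any(abs(rs - 1) > tol)) {
    stop(sprintf("cycle %d: transition matrix rows must sum to 1 (max |error| %.3g)",
                 cycle, max(abs(rs - 1))), call. = FALSE)
  }
  if (any(abs(m[.S_DEATH, ] - c(0, 0, 0, 1)) > tol)) {
    stop(sprintf("cycle %d: death must be absorbing", cycle), call. = FALSE)
  }
  if (m[.S_REL, .S_ON] > tol || m[.S_REL, .S_OFF] > tol) {
    stop(sprintf("cycle %d: relapse cannot revert to a stable state", cycle),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Per-cycle transition schedule for one treatment arm
#'
#' Bundles one row-stochastic 4x4 transition matrix per monthly cycle.
#' Validation is strict: rows must sum to 1 within 1e-12, death must be
#' absorbing, and relapse must not revert to a stable state; matrices
#' failing validation are rejected rather than renormalised.
#'
#' @param arm arm label (e.g. `"ipilimumab"` or `"hdi"`).
#' @param matrices list of 4x4 row-stochastic matrices, one per cycle,
#'   ordered from cycle 0.
#' @return An object of class `transition_schedule`.
#' @export
transition_schedule <- function(arm, matrices) {
  stopifnot(is.character(arm), length(arm) == 1L, is.list(matrices))
  if (length(matrices) < 1L) stop("schedule needs at least one cycle", call. = FALSE)
  for (i in seq_along(matrices)) {
    validate_transition_matrix(matrices[[i]], cycle = i - 1L)
  }
  structure(list(arm = arm, matrices = matrices),
            class = "transition_schedule")
}

#' @export
print.transition_schedule <- function(x, ...) {
  cat(sprintf("<transition_schedule> arm '%s', %d monthly cycles\n",
              x$arm, length(x$matrices)))
  invisible(x)
}

#' @export
length.transition_schedule <- function(x) length(x$matrices)

#' Run the deterministic cohort simulation
#'
#' Propagates a unit cohort through the transition schedule:
#' `occupancy[m + 1] = occupancy[m] %*% matrix[m]`, with occupancy measured
#' at cycle boundaries. Half-cycle-corrected state membership for cycle `m`
#' is the mean of the occupancy at its two boundaries, approximating
#' mid-cycle transitions.
#'
#' @param schedule a [transition_schedule()].
#' @param initial_state label of the entry state; the whole cohort starts
#'   there (the trial cohort enters on treatment).
#' @param horizon a [horizon_config()].
#' @return An object of class `cohort_trace` with `occupancy`
#'   (`(cycles + 1) x 4`) and `membership` (`cycles x 4`) matrices.
#' @export
run_cohort <- function(schedule, initial_state = "stable_on", horizon) {
  stopifnot(inherits(schedule, "transition_schedule"),
            inherits(horizon, "horizon_config"))
  if (!initial_state %in% health_states) {
    stop(sprintf("unknown initial state '%s'", initial_state), call. = FALSE)
  }
  cycles <- horizon$cycles
  if (length(schedule$matrices) < cycles) {
    stop(sprintf("schedule covers %d cycles but horizon needs %d",
                 length(schedule$matrices), cycles), call. = FALSE)
  }
  occ <- matrix(0, nrow = cycles + 1L, ncol = 4L,
                dimnames = list(NULL, health_states))
  occ[1L, match(initial_state, health_states)] <- 1
  for (m in seq_len(cycles)) {
    occ[m + 1L, ] <- occ[m, , drop = TRUE] %*% schedule$matrices[[m]]
  }
  membership <- (occ[seq_len(cycles), , drop = FALSE] +
                   occ[seq_len(cycles) + 1L, , drop = FALSE]) / 2
  structure(list(arm = schedule$arm, occupancy = occ, membership = membership,
                 cycles = cycles),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("<cohort_trace> arm '%s', %d cycles; final state occupancy:\n",
              x$arm, x$cycles))
  print(round(x$occupancy[x$cycles + 1L, ], 4))
  invisible(x)
}

#' Model-predicted survival curves
#'
#' Overall survival at each cycle boundary is the fraction of the cohort not
#' in the death state; progression-free survival is the fraction in either
#' stable state.
#'
#' @param trace a [run_cohort()] result.
#' @return Data frame with columns `month`, `os`, `pfs` for months
#'   `0..cycles`.
#' @export
model_survival <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  occ <- trace$occupancy
  data.frame(
    month = 0:trace$cycles,
    os = 1 - occ[, .S_DEATH],
    pfs = occ[, .S_ON] + occ[, .S_OFF]
  )
}

#' Per-cycle discount factors
#'
#' State-attached rewards (disease-management costs, QALYs) accrue over the
#' whole cycle and are discounted at the cycle midpoint,
#' `(1 + r)^(-(m + 0.5)/12)`; event costs (drug administrations, the
#' one-time palliative cost) are discounted at the cycle start,
#' `(1 + r)^(-m/12)`.
#'
#' @param horizon a [horizon_config()].
#' @return Data frame with columns `cycle` (0-based), `start`, `midpoint`.
#' @export
discount_factors <- function(horizon) {
  stopifnot(inherits(horizon, "horizon_config"))
  r <- horizon$discount_annual
  m <- 0:(horizon$cycles - 1L)
  data.frame(
    cycle = m,
    start = (1 + r)^(-m / 12),
    midpoint = (1 + r)^(-(m + 0.5) / 12)
  )
}

#' Export a cohort trace to CSV
#'
#' Long-format export with one row per cycle and state, carrying occupancy
#' at the start of the cycle, half-cycle membership and the midpoint
#' discount factor.
#'
#' @param trace a [run_cohort()] result.
#' @param horizon the [horizon_config()] used to produce the trace.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_trace_csv <- function(trace, horizon, path) {
  stopifnot(inherits(trace, "cohort_trace"))
  df <- discount_factors(horizon)
  cycles <- trace$cycles
  out <- data.frame(
    cycle = rep(0:(cycles - 1L), times = 4L),
    state = rep(health_states, each = cycles),
    occupancy = as.vector(trace$occupancy[seq_len(cycles), ]),
    membership = as.vector(trace$membership),
    discount_factor = rep(df$midpoint, times = 4L)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
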