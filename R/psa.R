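#' Parameter distributions for probabilistic sensitivity analysis
#'
#' Gamma distributions for costs (and age), beta distributions for
#' utilities, disutility tolls and transition probabilities, and a
#' lognormal for the ipilimumab hazard ratio. Standard deviations come from
#' the 95% CI half-width divided by 1.96 where a CI is available, otherwise
#' `sd_frac` of the mean (base case 0.20, varied 0.10-0.40 in sensitivity
#' analyses). For the lognormal the stored `sd` is the log-scale standard
#' deviation derived from the CI.
#'
#' @param config parameter configuration.
#' @param sd_frac default SD as a fraction of the mean for parameters
#'   without a CI.
#' @return Data frame with columns `name`, `family`, `mean`, `sd`.
#' @export
psa_distributions <- function(config = default_config(),
                              sd_frac = config$psa_sd_frac) {
  gamma_keys <- c(grep("^(cost|soc)_", required_config_keys(), value = TRUE),
                  "age_start")
  beta_keys <- c("utility_stable_on", "utility_stable_off", "utility_relapse",
                 "disutility_tox_ipi", "disutility_tox_hdi",
                 "tox_monthly_ipi", "tox_monthly_hdi", "discontinuation_ipi")
  if (config$discontinuation_hdi > 0) {
    beta_keys <- c(beta_keys, "discontinuation_hdi")
  }
  sd_for <- function(key) {
    ci <- config$ci[[key]]
    if (!is.null(ci)) (ci[2] - ci[1]) / 2 / 1.96 else sd_frac * config[[key]]
  }
  rows <- lapply(c(gamma_keys, beta_keys), function(key) {
    data.frame(name = key,
               family = if (key %in% gamma_keys) "gamma" else "beta",
               mean = config[[key]], sd = sd_for(key))
  })
  hr_sdlog <- if (!is.null(config$hr_ci)) {
    (log(config$hr_ci[2]) - log(config$hr_ci[1])) / 2 / 1.96
  } else sd_frac
  rows <- c(rows, list(data.frame(name = "hr_os_ipi", family = "lognormal",
                                  mean = config$hr_os_ipi, sd = hr_sdlog)))
  out <- do.call(rbind, rows)
  out <- out[out$mean > 0 | out$family == "beta", ]  # drop zero-mean costs
  rownames(out) <- NULL
  out
}

#' Draw parameter sets from their assigned distributions
#'
#' Moment matching: gamma with `shape = (mean/sd)^2`,
#' `scale = sd^2/mean`; beta with `nu = mean(1-mean)/sd^2 - 1`,
#' `alpha = mean nu`, `beta = (1-mean) nu`; lognormal with
#' `meanlog = log(mean)` and `sdlog` as stored. A zero SD collapses to a
#' point mass at the mean; a beta SD too large to moment-match is an error
#' naming the parameter.
#'
#' @param distributions a [psa_distributions()] data frame.
#' @param n number of draws.
#' @param seed optional integer; when supplied the RNG is seeded so draws
#'   are reproducible.
#' @return Numeric matrix `n x nrow(distributions)` with named columns.
#' @export
sample_parameters <- function(distributions, n = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draws <- matrix(NA_real_, nrow = n, ncol = nrow(distributions),
                  dimnames = list(NULL, distributions$name))
  for (i in seq_len(nrow(distributions))) {
    m <- distributions$mean[i]
    s <- distributions$sd[i]
    fam <- distributions$family[i]
    draws[, i] <- if (s == 0 || (fam != "lognormal" && m == 0)) {
      rep(m, n)
    } else if (fam == "gamma") {
      stats::rgamma(n, shape = (m / s)^2, scale = s^2 / m)
    } else if (fam == "beta") {
      nu <- m * (1 - m) / s^2 - 1
      if (nu <= 0) {
        stop(sprintf("beta SD for '%s' is not moment-matchable (sd^2 >= mean(1-mean))",
                     distributions$name[i]), call. = FALSE)
      }
      stats::rbeta(n, m * nu, (1 - m) * nu)
    } else if (fam == "lognormal") {
      stats::rlnorm(n, meanlog = log(m), sdlog = s)
    } else {
      stop(sprintf("unknown family '%s'", fam), call. = FALSE)
    }
  }
  draws
}

# column getter that falls back to the base-case value when a parameter is
# not part of the draw matrix
draw_col <- function(draws, name, config, n) {
  if (name %in% colnames(draws)) draws[, name] else rep(config[[name]], n)
}

# Vectorised cohort engine: runs n calibrated cohort simulations for one
# arm in a single pass over cycles, each iteration carrying its own hazard
# multiplier, discontinuation hazard and entry age. Mirrors
# calibrate_schedule()/run_cohort()/trace_exposures() arithmetic so that
# degenerate draws reproduce the deterministic pipeline. Returns the
# discounted exposures needed by the cost/QALY accumulator plus a `bad`
# flag for iterations whose decomposition was infeasible.
psa_arm_exposures <- function(arm, h, q_frac, age, config, horizon) {
  n <- length(h)
  cycles <- horizon$cycles
  df <- discount_factors(horizon)
  followup <- min(config$followup_months, cycles)
  H_os <- cumulative_hazard(config$surv_breakpoints, config$os_hazards_hdi,
                            followup)
  H_pfs <- cumulative_hazard(config$surv_breakpoints, config$pfs_hazards_hdi,
                             followup)
  life <- config_life_table(config,
                            horizon_years = ceiling(config$horizon_years) + 1)
  q_month <- annual_to_cycle_prob(life$q_annual)
  q_mel_month <- annual_to_cycle_prob(life$q_melanoma)
  dosing <- build_dosing(arm)
  admin <- fee_w_ind <- fee_w_maint <- numeric(cycles)
  idx <- dosing$cycle + 1L
  idx <- idx[idx <= cycles]
  admin[idx] <- dosing$administrations[seq_along(idx)]
  dosed <- dosing$administrations > 0
  fee_w_ind[idx] <- as.numeric(dosing$phase == "induction" & dosed)[seq_along(idx)]
  fee_w_maint[idx] <- as.numeric(dosing$phase == "maintenance" & dosed)[seq_along(idx)]
  dur <- if (arm == "ipilimumab") config$treatment_cycles_ipi else config$treatment_cycles_hdi
  q_disc <- ifelse(q_frac > 0, 1 - (1 - q_frac)^(1 / dur), 0)

  occ1 <- rep(1, n); occ2 <- occ3 <- occ4 <- rep(0, n)
  E_admin <- E_ind <- E_maint <- M_on <- M_off <- M_rel <- D <- rep(0, n)
  bad <- rep(FALSE, n)
  r_carry <- rep(0, n)
  for (m in seq_len(cycles) - 1L) {
    age_idx <- pmin(pmax(floor(age + m / 12) - life$age[1L] + 1, 1), nrow(life))
    b_raw <- q_month[age_idx]
    if (m < followup) {
      os_prev <- exp(-H_os[m + 1L] * h); os_next <- exp(-H_os[m + 2L] * h)
      pfs_prev <- exp(-H_pfs[m + 1L] * h); pfs_next <- exp(-H_pfs[m + 2L] * h)
      e <- 1 - pfs_next / pfs_prev
      d <- 1 - os_next / os_prev
      b <- pmin(b_raw, d)
      s_pf <- occ1 + occ2
      alive <- s_pf + occ3
      deaths_needed <- pmax(0, alive - alive * os_next / os_prev)
      need_rel <- deaths_needed - s_pf * b
      topup <- need_rel > occ3
      d_rel <- ifelse(need_rel <= 0, b,
                      ifelse(topup, 1,
                             pmin(1, pmax(b, need_rel / pmax(occ3, 1e-300)))))
      b1 <- ifelse(topup & need_rel > 0,
                   b + (need_rel - occ3) / pmax(s_pf, 1e-300), b)
      bad <- bad | (b1 > 1 + 1e-9)
      b1 <- pmin(1, b1)
      r <- pmax(0, e - b1)
      if (m == followup - 1L) r_carry <- r
    } else {
      b <- b_raw
      if (config$extrapolation == "registry") {
        q_mel <- q_mel_month[age_idx]
        b1 <- 1 - (1 - b) * (1 - q_mel)
        d_rel <- b1
        r <- r_carry
      } else {
        b1 <- b
        d_rel <- b
        r <- rep(0, n)
      }
    }
    q <- if (m < dur) q_disc else rep(0, n)
    stay_on <- 1 - b1 - r - q
    bad <- bad | (stay_on < -1e-12)
    if (m == dur) {
      to_off <- q + stay_on
      stay_on <- rep(0, n)
    } else {
      to_off <- q
    }
    stay_off <- 1 - b1 - r
    new1 <- occ1 * stay_on
    new2 <- occ1 * to_off + occ2 * stay_off
    new3 <- (occ1 + occ2) * r + occ3 * (1 - d_rel)
    deaths <- (occ1 + occ2) * b1 + occ3 * d_rel
    new4 <- occ4 + deaths

    fs <- df$start[m + 1L]; fm <- df$midpoint[m + 1L]
    E_admin <- E_admin + admin[m + 1L] * occ1 * fs
    E_ind <- E_ind + fee_w_ind[m + 1L] * occ1 * fs
    E_maint <- E_maint + fee_w_maint[m + 1L] * occ1 * fs
    M_on <- M_on + (occ1 + new1) / 2 * fm
    M_off <- M_off + (occ2 + new2) / 2 * fm
    M_rel <- M_rel + (occ3 + new3) / 2 * fm
    D <- D + deaths * fs
    occ1 <- new1; occ2 <- new2; occ3 <- new3; occ4 <- new4
  }
  list(E_admin = E_admin, E_ind = E_ind, E_maint = E_maint,
       M_on = M_on, M_off = M_off, M_rel = M_rel, D = D, bad = bad)
}

# cost and QALY totals for one arm from vectorised exposures and a draw
# matrix (mirrors accumulate())
psa_arm_totals <- function(arm, ex, draws, config, perspective, n) {
  g <- function(key) draw_col(draws, key, config, n)
  soc <- perspective == "societal"
  if (arm == "ipilimumab") {
    drug <- g("cost_ipi_per_infusion") * ex$E_admin
    fees <- g("cost_infusion_ipi_induction") * ex$E_ind +
      g("cost_infusion_ipi_maintenance") * ex$E_maint
    visit <- (g("soc_time_ipi_induction") + g("soc_travel_ipi_induction")) * ex$E_ind +
      (g("soc_time_ipi_maintenance") + g("soc_travel_ipi_maintenance")) * ex$E_maint
    tox_p <- g("tox_monthly_ipi"); tox_c <- g("cost_toxicity_ipi")
    toll <- g("disutility_tox_ipi")
  } else {
    drug <- g("cost_hdi_induction") * ex$E_ind +
      g("cost_hdi_maintenance") * ex$E_maint
    fees <- g("cost_infusion_hdi_induction") * ex$E_ind +
      g("cost_infusion_hdi_maintenance") * ex$E_maint
    visit <- (g("soc_time_hdi_induction") + g("soc_travel_hdi_induction")) * ex$E_ind +
      (g("soc_time_hdi_maintenance") + g("soc_travel_hdi_maintenance")) * ex$E_maint
    tox_p <- g("tox_monthly_hdi"); tox_c <- g("cost_toxicity_hdi")
    toll <- g("disutility_tox_hdi")
  }
  stable_exposure <- ex$M_off +
    if (isTRUE(config$stable_cost_on_treatment)) ex$M_on else 0
  cost <- drug + fees +
    g("cost_stable") * stable_exposure +
    tox_p * tox_c * ex$M_on +
    g("cost_progressed") * ex$M_rel +
    g("cost_palliative_death") * ex$D
  if (soc) {
    off_addon <- g("soc_time_stable_off") + g("soc_travel_stable_off")
    cost <- cost + visit + off_addon * ex$M_off +
      g("soc_caregiver") * (ex$M_on + ex$M_off + ex$M_rel)
  }
  qaly <- (g("utility_stable_on") * ex$M_on +
             g("utility_stable_off") * ex$M_off +
             g("utility_relapse") * ex$M_rel) / 12 -
    toll / 12 * tox_p * ex$M_on
  list(cost = cost, qaly = qaly)
}

psa_iteration_results <- function(draws, config, perspective) {
  n <- nrow(draws)
  horizon <- horizon_config(config$horizon_years, config$discount_annual)
  h <- draw_col(draws, "hr_os_ipi", config, n)
  age <- draw_col(draws, "age_start", config, n)
  q_ipi <- draw_col(draws, "discontinuation_ipi", config, n)
  q_hdi <- draw_col(draws, "discontinuation_hdi", config, n)
  ex_hdi <- psa_arm_exposures("hdi", rep(1, n), q_hdi, age, config, horizon)
  ex_ipi <- psa_arm_exposures("ipilimumab", h, q_ipi, age, config, horizon)
  tot_hdi <- psa_arm_totals("hdi", ex_hdi, draws, config, perspective, n)
  tot_ipi <- psa_arm_totals("ipilimumab", ex_ipi, draws, config, perspective, n)
  list(cost_hdi = tot_hdi$cost, qaly_hdi = tot_hdi$qaly,
       cost_ipi = tot_ipi$cost, qaly_ipi = tot_ipi$qaly,
       bad = ex_hdi$bad | ex_ipi$bad)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo over the parameter distributions (base case 100,000
#' iterations). Each iteration draws a full parameter set, rescales the
#' ipilimumab arm's survival through the drawn hazard ratio, recalibrates
#' and re-runs both arms' cohorts (a single vectorised pass over cycles
#' carries all iterations), and records incremental cost and QALY. The
#' cost-effectiveness acceptability curve reports, at each willingness-to-
#' pay value, the fraction of iterations in which each arm has the higher
#' net monetary benefit (ties favour the reference arm, so the two
#' fractions sum to 1). Infeasible draws are resampled and counted;
#' resampling beyond 1% of the iteration count aborts.
#'
#' @param config parameter configuration.
#' @param iterations number of Monte Carlo iterations.
#' @param seed integer seed; identical seeds give identical results.
#' @param wtp_grid willingness-to-pay grid (USD/QALY, strictly increasing;
#'   must include 100,000 and 200,000).
#' @param sd_frac default SD fraction for parameters without a CI.
#' @param perspective cost perspective.
#' @return Object of class `psa_result` with per-iteration `delta_cost`,
#'   `delta_qaly`, arm totals, the `ceac` data frame and bookkeeping
#'   (`iterations`, `seed`, `resampled`).
#' @export
run_psa <- function(config = default_config(),
                    iterations = config$psa_iterations, seed = 1L,
                    wtp_grid = c(25000, 50000, 75000, 100000, 125000,
                                 150000, 175000, 200000, 300000, 400000,
                                 500000),
                    sd_frac = config$psa_sd_frac, perspective = NULL) {
  stopifnot(iterations >= 1)
  if (any(wtp_grid <= 0) || is.unsorted(wtp_grid, strictly = TRUE)) {
    stop("`wtp_grid` must be positive and strictly increasing", call. = FALSE)
  }
  if (!all(c(100000, 200000) %in% wtp_grid)) {
    stop("`wtp_grid` must include 100,000 and 200,000", call. = FALSE)
  }
  if (is.null(perspective)) perspective <- config$perspective
  validate_config(config)
  dists <- psa_distributions(config, sd_frac)
  set.seed(seed)
  draws <- sample_parameters(dists, n = iterations)
  res <- psa_iteration_results(draws, config, perspective)
  resampled <- 0L
  while (any(res$bad)) {
    idx <- which(res$bad)
    resampled <- resampled + length(idx)
    if (resampled > max(1, 0.01 * iterations)) {
      stop(sprintf("more than 1%% of PSA draws infeasible (%d resampled)",
                   resampled), call. = FALSE)
    }
    redraw <- sample_parameters(dists, n = length(idx))
    sub <- psa_iteration_results(redraw, config, perspective)
    for (f in c("cost_hdi", "qaly_hdi", "cost_ipi", "qaly_ipi")) {
      res[[f]][idx] <- sub[[f]]
    }
    res$bad[idx] <- sub$bad
  }
  delta_cost <- res$cost_ipi - res$cost_hdi
  delta_qaly <- res$qaly_ipi - res$qaly_hdi
  p_ipi <- vapply(wtp_grid, function(w) {
    mean(w * delta_qaly - delta_cost > 0)
  }, numeric(1))
  ceac <- data.frame(wtp = wtp_grid, p_hdi = 1 - p_ipi, p_ipi = p_ipi)
  structure(list(
    delta_cost = delta_cost, delta_qaly = delta_qaly,
    cost_hdi = res$cost_hdi, qaly_hdi = res$qaly_hdi,
    cost_ipi = res$cost_ipi, qaly_ipi = res$qaly_ipi,
    ceac = ceac, iterations = iterations, seed = seed,
    resampled = resampled, perspective = perspective
  ), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations (seed %s, %d resampled)\n",
              x$iterations, format(x$seed), x$resampled))
  cat(sprintf("  mean incremental cost $%s, mean incremental QALY %.4f\n",
              format(round(mean(x$delta_cost)), big.mark = ","),
              mean(x$delta_qaly)))
  i100 <- match(100000, x$ceac$wtp)
  i200 <- match(200000, x$ceac$wtp)
  cat(sprintf("  HDI cost-effective %.1f%% of the time at $100,000/QALY, %.1f%% at $200,000/QALY\n",
              100 * x$ceac$p_hdi[i100], 100 * x$ceac$p_hdi[i200]))
  invisible(x)
}
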