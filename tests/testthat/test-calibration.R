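test_that("Kaplan-Meier decrements and annual-to-monthly conversion are exact", {
  expect_equal(monthly_event_prob(1.0, 0.9), 0.1)
  expect_equal(monthly_event_prob(0.9, 0.81), 0.1)
  expect_equal(monthly_event_prob(0.7, 0.7), 0)
  expect_error(monthly_event_prob(0.8, 0.9), "increase")
  expect_error(monthly_event_prob(0, 0), "positive")
  expect_equal(annual_to_cycle_prob(0), 0)
  expect_equal(annual_to_cycle_prob(1), 1)
  expect_equal(annual_to_cycle_prob(0.12, 12), 1 - 0.88^(1 / 12))
  expect_error(annual_to_cycle_prob(1.2), "\\[0, 1\\]")
})

test_that("constant-hazard discontinuation matches a root-finding oracle", {
  solve_q <- function(fraction, duration) {
    uniroot(function(q) 1 - (1 - q)^duration - fraction,
            c(0, 1 - 1e-9), tol = 1e-12)$root
  }
  expect_equal(discontinuation_monthly_prob(0, 14), 0)
  expect_equal(discontinuation_monthly_prob(0.391, 14), solve_q(0.391, 14),
               tolerance = 1e-9)
  expect_equal(discontinuation_monthly_prob(0.60, 14), solve_q(0.60, 14),
               tolerance = 1e-9)
  course <- treatment_course("ipilimumab", 14, 0.391)
  expect_equal(discontinuation_monthly_prob(course),
               discontinuation_monthly_prob(0.391, 14))
  expect_error(treatment_course("x", 14, 1), "\\[0, 1\\)")
})

test_that("calibration reproduces constant-hazard targets to near machine precision", {
  targets <- constant_hazard_targets(h_os = -log(0.99), h_pfs = -log(0.98))
  course <- treatment_course("toy", 14, 0)
  hz <- horizon_config(78 / 12, 0)
  sched <- calibrate_schedule(targets, course, zero_life_table(),
                              mode = "registry", horizon = hz)
  surv <- model_survival(run_cohort(sched, "stable_on", hz))
  expect_lt(max(abs(surv$os - targets$os)), 1e-10)
  expect_lt(max(abs(surv$pfs - targets$pfs)), 1e-10)
  # recovered decrements match the generating hazards
  e <- monthly_event_prob(surv$pfs[-79], surv$pfs[-1])
  d <- monthly_event_prob(surv$os[-79], surv$os[-1])
  expect_lt(max(abs(e - 0.02)), 1e-6)
  expect_lt(max(abs(d - 0.01)), 1e-6)
  # the schedule's progression-free exit probability equals the PFS decrement
  exit <- vapply(sched$matrices[1:78],
                 function(m) m[1, "relapse"] + m[1, "death"], numeric(1))
  expect_lt(max(abs(exit - 0.02)), 1e-6)
})

test_that("round-trip calibration holds for both synthetic trial arms", {
  cfg <- default_config()
  hz <- horizon_config(cfg$horizon_years, cfg$discount_annual)
  life <- config_life_table(cfg)
  for (arm in c("hdi", "ipilimumab")) {
    targets <- generate_targets(arm_survival_spec(arm, cfg),
                                cfg$followup_months)
    econ <- arm_economics(arm, cfg)
    sched <- calibrate_schedule(targets, econ$course, life, "registry",
                                hz, start_age = cfg$age_start)
    surv <- model_survival(run_cohort(sched, "stable_on", hz))
    keep <- seq_len(cfg$followup_months + 1)
    expect_lt(max(abs(surv$os[keep] - targets$os)), 1e-8)
    expect_lt(max(abs(surv$pfs[keep] - targets$pfs)), 1e-8)
    expect_true(all(abs(rowSums(run_cohort(sched, "stable_on", hz)$occupancy) - 1) < 1e-9))
  }
})

test_that("identical OS and PFS targets leave the relapse state empty", {
  h <- -log(0.99)
  targets <- constant_hazard_targets(h_os = h, h_pfs = h)
  hz <- horizon_config(78 / 12, 0)
  life <- life_table(54:140, 0.005, 0)
  sched <- calibrate_schedule(targets, treatment_course("toy", 14, 0.391),
                              life, "registry", hz)
  trace <- run_cohort(sched, "stable_on", hz)
  expect_true(all(trace$occupancy[, "relapse"] < 1e-12))
  surv <- model_survival(trace)
  expect_lt(max(abs(surv$os - targets$os)), 1e-10)
})

test_that("extrapolation is continuous at follow-up and cure dominates registry", {
  cfg <- default_config()
  hz <- horizon_config(cfg$horizon_years, cfg$discount_annual)
  life <- config_life_table(cfg)
  targets <- generate_targets(arm_survival_spec("hdi", cfg), cfg$followup_months)
  course <- arm_economics("hdi", cfg)$course
  surv <- lapply(c("registry", "cure"), function(mode) {
    sched <- calibrate_schedule(targets, course, life, mode, hz,
                                start_age = cfg$age_start)
    model_survival(run_cohort(sched, "stable_on", hz))
  })
  m78 <- 1:79
  expect_equal(surv[[1]]$os[m78], surv[[2]]$os[m78], tolerance = 1e-12)
  # no discontinuity: the monthly decrement just after follow-up stays in
  # the range spanned by its neighbours
  dec <- -diff(surv[[1]]$os)
  expect_lt(abs(dec[79]), max(dec[77:78]) + 0.01)
  after <- 80:121
  expect_true(all(surv[[2]]$os[after] >= surv[[1]]$os[after]))
  expect_gt(min(surv[[2]]$os[after] - surv[[1]]$os[after]), 0)
})

test_that("a proportional-hazards advantage is preserved through calibration", {
  cfg <- default_config()
  hz <- horizon_config(cfg$horizon_years, cfg$discount_annual)
  os_hdi <- model_survival(run_arm("hdi", cfg)$trace)$os
  os_ipi <- model_survival(run_arm("ipilimumab", cfg)$trace)$os
  expect_true(all(os_ipi >= os_hdi - 1e-12))
})

test_that("an impossible schedule is reported with its cycle", {
  targets <- constant_hazard_targets(h_os = -log(0.7), h_pfs = -log(0.6),
                                     months = 12)
  hz <- horizon_config(1, 0)
  course <- treatment_course("toy", 2, 0.97)  # per-cycle hazard ~0.83
  expect_error(
    calibrate_schedule(targets, course, zero_life_table(), "registry", hz),
    "infeasible at cycle 0")
  expect_error(
    calibrate_schedule(constant_hazard_targets(-log(0.98), -log(0.99), 12),
                       treatment_course("toy", 2, 0), zero_life_table(),
                       "registry", hz),
    "PFS target exceeds OS")
})

test_that("toxicity incidence compounds on on-treatment membership and plateaus", {
  hz <- horizon_config(1, 0)
  trace <- run_cohort(identity_schedule(12), "stable_on", hz)
  none <- toxicity_incidence(treatment_course("toy", 12, 0, 0), trace)
  expect_true(all(none == 0))
  cum <- toxicity_incidence(treatment_course("toy", 12, 0, 0.1), trace)
  expect_equal(cum[1:2], c(0.1, 0.19))
  expect_equal(cum, 1 - 0.9^(1:12))
  # after the forced stop nobody is on treatment, so the curve is flat
  cfg <- default_config()
  arm <- run_arm("ipilimumab", cfg)
  tox <- toxicity_incidence(arm$arm_econ$course, arm$trace)
  expect_true(all(diff(tox) >= -1e-15))
  expect_equal(tox[30], tox[120], tolerance = 1e-12)
})

test_that("targets and life tables survive a CSV round trip", {
  cfg <- default_config()
  targets <- generate_targets(arm_survival_spec("hdi", cfg), 24)
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "targets.csv")
  write.csv(format(as.data.frame(targets), digits = 15, trim = TRUE), p1,
            row.names = FALSE, quote = FALSE)
  back <- read_survival_targets(p1)
  expect_equal(back$os, targets$os, tolerance = 1e-12)
  life <- config_life_table(cfg, 5)
  p2 <- file.path(dir, "life.csv")
  write.csv(as.data.frame(life), p2, row.names = FALSE, quote = FALSE)
  expect_equal(read_life_table(p2)$q_annual, life$q_annual)
  sched <- identity_schedule(2)
  p3 <- file.path(dir, "sched.csv")
  write_schedule_csv(sched, p3)
  got <- read.csv(p3)
  expect_equal(nrow(got), 2 * 16)
  expect_equal(sum(got$probability), 8)  # two cycles of row-stochastic identity
})
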