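test_that("dosing schedules carry the trial dose counts", {
  ipi <- build_dosing("ipilimumab")
  expect_equal(sum(ipi$administrations), 8)
  expect_equal(sum(ipi$administrations[ipi$phase == "induction"]), 4)
  expect_equal(which(ipi$administrations > 0 & ipi$phase == "maintenance") - 1,
               c(5, 8, 11, 14))
  hdi <- build_dosing("hdi")
  expect_equal(sum(hdi$phase == "induction"), 1)
  expect_equal(sum(hdi$phase == "maintenance"), 12)
  expect_error(build_dosing("nivolumab"), "unknown arm")
})

test_that("per-member cycle costs add up from the published components", {
  cfg <- default_config()
  cfg$tox_monthly_ipi <- 0
  econ <- arm_economics("ipilimumab", cfg)
  expect_equal(cycle_cost("stable_off", 3, econ, "healthcare"), 1066)
  expect_equal(cycle_cost("relapse", 3, econ, "healthcare"), 11365)
  expect_equal(cycle_cost("death", 3, econ, "healthcare"), 0)
  # maintenance cycle 5 carries one infusion: drug + fee + stable disease
  expect_equal(cycle_cost("stable_on", 5, econ, "healthcare"),
               54850 + 49 + 1066)
  # induction cycle 0 carries two infusions
  expect_equal(cycle_cost("stable_on", 0, econ, "healthcare"),
               2 * 54850 + 196 + 1066)
  # societal perspective adds visit and caregiver costs
  expect_equal(cycle_cost("stable_off", 3, econ, "societal"),
               1066 + 153 + 49 + 619)
})

test_that("palliative cost scales linearly with the dying mass", {
  expect_equal(death_transition_cost(0), 0)
  expect_equal(death_transition_cost(1), 22731)
  expect_equal(death_transition_cost(0.5) + death_transition_cost(0.5),
               death_transition_cost(1))
  expect_error(death_transition_cost(1.5), "\\[0, 1\\]")
})

test_that("cycle QALYs follow annual utilities and toxicity tolls", {
  u <- list(stable_on = 0.83, stable_off = 0.96, relapse = 0.52, death = 0)
  expect_equal(12 * cycle_qaly("relapse", 0, u), 0.52)
  expect_equal(cycle_qaly("death", 0, u), 0)
  expect_equal(cycle_qaly("stable_on", 1, u, toll = 0.0134),
               (0.83 - 0.0134) / 12)
  expect_equal(cycle_qaly("stable_on", 0.5, u, toll = 0.0134),
               (0.83 - 0.0134 / 2) / 12)
})

test_that("accumulation matches closed-form annuities for an immortal cohort", {
  cfg <- default_config()
  econ <- arm_economics("hdi", cfg)
  hz0 <- horizon_config(10, 0)
  trace <- run_cohort(identity_schedule(120), "stable_off", hz0)
  tot <- accumulate(trace, econ, hz0, "healthcare")
  expect_equal(tot$qaly, 9.6)
  expect_equal(tot$cost, 120 * 1066)
  hz3 <- horizon_config(10, 0.03)
  tot3 <- accumulate(run_cohort(identity_schedule(120), "stable_off", hz3),
                     econ, hz3, "healthcare")
  annuity <- (1 - 1.03^(-10)) / log(1.03)
  expect_equal(tot3$qaly, 0.96 * annuity, tolerance = 0.002)
  # zero-cost configuration
  zero <- cfg
  for (k in grep("^(cost|soc)_", names(zero), value = TRUE)) zero[[k]] <- 0
  tot0 <- accumulate(trace, arm_economics("hdi", zero), hz0, "societal")
  expect_equal(tot0$cost, 0)
})

test_that("totals respond monotonically to costs, perspective and discounting", {
  cfg <- default_config()
  for (arm in c("hdi", "ipilimumab")) {
    base <- run_arm(arm, cfg, "healthcare")
    soc <- run_arm(arm, cfg, "societal")
    expect_gte(soc$cost, base$cost)
    expect_equal(soc$qaly, base$qaly)
    undisc <- cfg; undisc$discount_annual <- 0
    free <- run_arm(arm, undisc, "healthcare")
    expect_gte(free$cost, base$cost)
    expect_gte(free$qaly, base$qaly)
    # QALYs cannot exceed undiscounted alive person-years at best utility
    alive_years <- sum(free$trace$membership[, 1:3]) / 12
    expect_lte(base$qaly, alive_years * 0.96)
    for (key in c("cost_ipi_per_infusion", "cost_stable", "cost_progressed",
                  "cost_palliative_death", "cost_toxicity_hdi",
                  "cost_hdi_maintenance")) {
      up <- cfg
      up[[key]] <- cfg[[key]] * 1.1
      expect_gte(run_arm(arm, up, "healthcare")$cost, base$cost - 1e-9)
    }
  }
})
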