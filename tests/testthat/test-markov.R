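test_that("identity transitions leave the cohort where it started", {
  hz <- horizon_config(2, 0)
  trace <- run_cohort(identity_schedule(hz$cycles), "stable_on", hz)
  expect_true(all(trace$occupancy[, "stable_on"] == 1))
  expect_true(all(trace$occupancy[, "death"] == 0))
  surv <- model_survival(trace)
  expect_true(all(surv$os == 1) && all(surv$pfs == 1))
})

test_that("a constant monthly death probability decays the cohort geometrically", {
  hz <- horizon_config(2 / 12, 0)
  sched <- transition_schedule("toy", replicate(2, death_only_matrix(0.1),
                                                simplify = FALSE))
  trace <- run_cohort(sched, "stable_on", hz)
  alive <- 1 - trace$occupancy[, "death"]
  expect_equal(unname(alive), c(1, 0.9, 0.81))
  expect_equal(unname(model_survival(trace)$os), c(1, 0.9, 0.81))
  # half-cycle membership is the trapezoid of the two boundary occupancies
  expect_equal(unname(trace$membership[1, "stable_on"]), 0.95)
})

test_that("occupancy equals the matrix-power oracle for a constant matrix", {
  m <- matrix(c(
    0.92, 0.03, 0.03, 0.02,
    0,    0.95, 0.03, 0.02,
    0,    0,    0.94, 0.06,
    0,    0,    0,    1
  ), nrow = 4, byrow = TRUE, dimnames = list(health_states, health_states))
  cycles <- 120L
  hz <- horizon_config(10, 0.03)
  trace <- run_cohort(transition_schedule("toy", replicate(cycles, m,
                                                           simplify = FALSE)),
                      "stable_on", hz)
  v <- c(1, 0, 0, 0)
  pow <- diag(4)
  for (k in seq_len(cycles)) {
    pow <- pow %*% m
    expect_lt(max(abs(trace$occupancy[k + 1, ] - as.vector(v %*% pow))), 1e-12)
  }
  # conservation and monotone death
  expect_true(all(abs(rowSums(trace$occupancy) - 1) < 1e-9))
  expect_true(all(diff(trace$occupancy[, "death"]) >= -1e-15))
  surv <- model_survival(trace)
  expect_true(all(surv$pfs <= surv$os + 1e-12))
})

test_that("invalid schedules and mismatched horizons are rejected", {
  bad <- diag(4); bad[1, 1] <- 0.5         # row sums 0.5
  expect_error(transition_schedule("toy", list(bad)), "sum to 1")
  rel <- death_only_matrix(0); rel[3, 1] <- 0.2; rel[3, 3] <- 0.8
  expect_error(transition_schedule("toy", list(rel)), "relapse")
  dead <- death_only_matrix(0); dead[4, ] <- c(0.1, 0, 0, 0.9)
  expect_error(transition_schedule("toy", list(dead)), "absorbing")
  hz <- horizon_config(1, 0)
  expect_error(run_cohort(identity_schedule(3), "stable_on", hz),
               "covers 3 cycles")
  expect_error(run_cohort(identity_schedule(12), "limbo", hz), "unknown")
})

test_that("discount factors follow the annual rate and cycle convention", {
  expect_true(all(discount_factors(horizon_config(2, 0))$midpoint == 1))
  df <- discount_factors(horizon_config(2, 0.03))
  expect_equal(df$start[df$cycle == 12], 1 / 1.03)
  expect_equal(df$midpoint[df$cycle == 0], 1.03^(-0.5 / 12))
  expect_true(all(diff(df$start) < 0) && all(diff(df$midpoint) < 0))
  expect_error(horizon_config(10, -0.01), "non-negative")
})

test_that("total alive membership equals the trapezoidal integral of survival", {
  cfg <- default_config()
  hz <- horizon_config(cfg$horizon_years, cfg$discount_annual)
  arm <- run_arm("hdi", cfg)
  os <- model_survival(arm$trace)$os
  alive_membership <- sum(arm$trace$membership[, 1:3])
  trapezoid <- sum((os[-1] + os[-length(os)]) / 2)
  expect_equal(alive_membership, trapezoid, tolerance = 1e-12)
})

test_that("trace CSV export carries every cycle, state and discount factor", {
  hz <- horizon_config(1, 0.03)
  trace <- run_cohort(identity_schedule(12), "stable_on", hz)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(trace, hz, path)
  got <- read.csv(path)
  expect_equal(nrow(got), 12 * 4)
  expect_setequal(unique(got$state), health_states)
  expect_equal(got$occupancy[got$state == "stable_on"], rep(1, 12))
  expect_equal(got$discount_factor[got$cycle == 0],
               rep(1.03^(-0.5 / 12), 4))
})
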