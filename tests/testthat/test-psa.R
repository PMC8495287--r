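test_that("moment matching maps means and SDs onto the sampling distributions", {
  gam <- data.frame(name = "cost_ipi_per_infusion", family = "gamma",
                    mean = 54850, sd = 0.2 * 54850)
  set.seed(42)
  x <- sample_parameters(gam, 5)
  set.seed(42)
  expect_identical(as.vector(x), rgamma(5, shape = 25, scale = 2194))
  bet <- data.frame(name = "utility_relapse", family = "beta",
                    mean = 0.52, sd = (0.61 - 0.44) / 2 / 1.96)
  nu <- 0.52 * 0.48 / bet$sd^2 - 1
  expect_equal(0.52 * nu, 68.4916, tolerance = 1e-4)
  expect_equal(0.48 * nu, 63.2230, tolerance = 1e-4)
  set.seed(7)
  y <- sample_parameters(bet, 5)
  set.seed(7)
  expect_identical(as.vector(y), rbeta(5, 0.52 * nu, 0.48 * nu))
  # zero SD collapses to the mean
  gam$sd <- 0
  expect_equal(as.vector(sample_parameters(gam, 3)), rep(54850, 3))
  bad <- data.frame(name = "utility_relapse", family = "beta",
                    mean = 0.52, sd = 0.6)
  expect_error(sample_parameters(bad, 1), "utility_relapse")
})

test_that("distribution table uses CI half-widths and the default SD fraction", {
  cfg <- default_config()
  d <- psa_distributions(cfg)
  ipi <- d[d$name == "cost_ipi_per_infusion", ]
  expect_equal(ipi$sd, (76351 - 33349) / 2 / 1.96)
  age <- d[d$name == "age_start", ]
  expect_equal(age$sd, 0.2 * 54)
  expect_equal(age$family, "gamma")
  hr <- d[d$name == "hr_os_ipi", ]
  expect_equal(hr$family, "lognormal")
  expect_equal(hr$sd, (log(0.99) - log(0.61)) / 2 / 1.96)
  narrow <- psa_distributions(cfg, sd_frac = 0.1)
  expect_equal(narrow$sd[narrow$name == "age_start"], 0.1 * 54)
})

test_that("a degenerate PSA reproduces the deterministic base case", {
  cfg <- degenerate_config()
  base <- run_base_case(cfg)
  psa <- run_psa(cfg, iterations = 8, seed = 11, sd_frac = 0)
  expect_equal(mean(psa$delta_cost), base$delta_cost, tolerance = 1e-12)
  expect_equal(mean(psa$delta_qaly), base$delta_qaly, tolerance = 1e-12)
  expect_equal(max(abs(psa$cost_hdi - base$cost_ref)), 0, tolerance = 1e-6)
  # CEAC degenerates to a step at the base-case ICER
  expect_true(all(psa$ceac$p_hdi %in% c(0, 1)))
  expect_equal(psa$ceac$p_hdi, as.numeric(psa$ceac$wtp < base$icer_raw))
})

test_that("seeded PSA runs are identical and CEAC fractions are complementary", {
  cfg <- default_config()
  a <- run_psa(cfg, iterations = 1500, seed = 3)
  b <- run_psa(cfg, iterations = 1500, seed = 3)
  expect_identical(a$delta_cost, b$delta_cost)
  expect_identical(a$ceac, b$ceac)
  expect_equal(a$ceac$p_hdi + a$ceac$p_ipi, rep(1, nrow(a$ceac)))
  c2 <- run_psa(cfg, iterations = 1500, seed = 4)
  se <- sqrt(pmax(a$ceac$p_hdi * (1 - a$ceac$p_hdi), 1e-4) / 1500) +
    sqrt(pmax(c2$ceac$p_hdi * (1 - c2$ceac$p_hdi), 1e-4) / 1500)
  expect_true(all(abs(a$ceac$p_hdi - c2$ceac$p_hdi) <= 3 * se))
})

test_that("the reference arm is preferred at low willingness-to-pay when cheaper", {
  cfg <- default_config()
  psa <- run_psa(cfg, iterations = 1000, seed = 5,
                 wtp_grid = c(1000, 100000, 200000))
  # HDI costs less in essentially every draw, so tiny WTP favours it
  expect_gt(psa$ceac$p_hdi[1], 0.99)
  expect_true(all(diff(psa$ceac$p_hdi) <= 0))
  expect_equal(psa$resampled, 0)
})

test_that("willingness-to-pay grids are validated", {
  cfg <- default_config()
  expect_error(run_psa(cfg, 10, 1, wtp_grid = c(100000, 200000, 150000)),
               "increasing")
  expect_error(run_psa(cfg, 10, 1, wtp_grid = c(50000, 200000)),
               "100,000")
})
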