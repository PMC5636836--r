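test_that("predation count follows P = MR * F / E", {
  expect_equal(predation_count(3.3e8, 0.25, 8246.664),
               3.3e8 * 0.25 / 8246.664, tolerance = 1e-12)
  expect_equal(predation_count(3.3e8, 0, 8247), 0)
  expect_equal(predation_count(2 * 3.3e8, 0.25, 8247),
               2 * predation_count(3.3e8, 0.25, 8247), tolerance = 1e-12)
  expect_error(predation_count(1e8, 0.25, 0), "positive")
  expect_error(predation_count(1e8, 1.5, 100))
})

test_that("scenario runs are bit-identical under a fixed seed", {
  pred <- fixture_predators(seed = 2, n = 60)
  st <- fixture_stomachs(seed = 2, n_stomachs = 60)
  cfg <- scenario_config(2, abundance_scenario("N1"), n_sims = 50, seed = 17)
  r1 <- run_scenario(cfg, pred, st)
  r2 <- run_scenario(cfg, pred, st)
  expect_identical(r1$draws, r2$draws)
  expect_identical(r1$summary, r2$summary)
  r3 <- run_scenario(scenario_config(2, abundance_scenario("N1"),
                                     n_sims = 50, seed = 18), pred, st)
  expect_false(identical(r1$draws, r3$draws))
})

test_that("energy is conserved per draw under compositional diet variants", {
  pred <- fixture_predators(seed = 2, n = 60)
  st <- fixture_stomachs(seed = 2, n_stomachs = 60)
  for (v in 2:3) {
    res <- run_scenario(scenario_config(v, abundance_scenario("N2"),
                                        n_sims = 100, seed = 5), pred, st)
    recon <- as.vector(res$draws %*% res$prey_energy_kj)
    expect_equal(recon, res$e_pop, tolerance = 1e-6)
  }
})

test_that("mean counts scale linearly with abundance", {
  pred <- fixture_predators(seed = 2, n = 60)
  cfg <- scenario_config(1, abundance_scenario("N2"), n_sims = 200, seed = 8)
  sw <- sensitivity_sweep(cfg, pred, axis = "abundance", grid = c(562, 1130))
  # matched seeds and a constant CV make the scaling exact
  expect_equal(sw$mean_count[2] / sw$mean_count[1], 1130 / 562,
               tolerance = 1e-9)
})

test_that("consumption increases with temperature and decreases with Q10 below the reference", {
  pred <- fixture_predators(seed = 2, n = 60)
  cfg <- scenario_config(1, abundance_scenario("N2"), n_sims = 100, seed = 8)
  sw_t <- sensitivity_sweep(cfg, pred, axis = "temperature",
                            grid = c(14.0, 16.7, 19.1))
  expect_true(all(diff(sw_t$mean_count) > 0))
  # below the 20 C reference a larger Q10 means stronger down-correction
  sw_q <- sensitivity_sweep(cfg, pred, axis = "q10", grid = c(1.3, 3.0))
  expect_lt(sw_q$mean_count[2], sw_q$mean_count[1])
  expect_error(sensitivity_sweep(cfg, pred, axis = "bogus", grid = 1))
})

test_that("a q10-fixed singleton sweep equals the default scenario run", {
  pred <- fixture_predators(seed = 2, n = 60)
  cfg <- scenario_config(1, abundance_scenario("N2"), n_sims = 100, seed = 8)
  base <- run_scenario(cfg, pred)
  sw <- sensitivity_sweep(cfg, pred, axis = "q10", grid = 2.2)
  expect_equal(sw$mean_count, base$summary$mean_count, tolerance = 1e-12)
})

test_that("widening parameter uncertainty never narrows the percentile CI", {
  pred <- fixture_predators(seed = 2, n = 60)
  narrow <- run_scenario(scenario_config(1, abundance_scenario("N2"),
                                         n_sims = 300, seed = 9), pred)
  wide <- run_scenario(scenario_config(1, abundance_scenario("N2"),
                                       n_sims = 300, seed = 9,
                                       uncertainty = list(q10 = TRUE)), pred)
  w_n <- narrow$summary$ci_high - narrow$summary$ci_low
  w_w <- wide$summary$ci_high - wide$summary$ci_low
  expect_gte(w_w, w_n)
})

test_that("flagged profiles are rejected unless overridden", {
  pred <- fixture_predators(seed = 2, n = 20)
  bad <- fixture_profiles(corrected = FALSE)
  cfg <- scenario_config(1, abundance_scenario("N1"), n_sims = 10, seed = 1)
  expect_error(run_scenario(cfg, pred, profiles = bad), "validation")
  expect_s3_class(run_scenario(cfg, pred, profiles = bad,
                               allow_flagged = TRUE), "scenario_result")
})

test_that("biomass equals mean count times mean mass", {
  pred <- fixture_predators(seed = 2, n = 60)
  res <- run_scenario(scenario_config(1, abundance_scenario("N2"),
                                      n_sims = 100, seed = 8), pred)
  b <- biomass_consumed(res)
  expect_equal(unname(b[["gummy_shark"]]),
               res$summary$mean_count[1] * 1.8 / 1000, tolerance = 1e-12)
  expect_equal(unname(b), res$summary$biomass_t, tolerance = 1e-12)
})

test_that("log-normal MLE recovers known parameters and handles edge cases", {
  set.seed(33)
  x <- rlnorm(1e4, meanlog = 9.3, sdlog = 0.4)
  fit <- fit_lognormal(x)
  expect_equal(fit$meanlog, 9.3, tolerance = 0.02)
  expect_equal(fit$sdlog, 0.4, tolerance = 0.02)
  # cross-check against an independent ML fitter
  ref <- MASS::fitdistr(x, "lognormal")
  expect_equal(fit$meanlog, unname(ref$estimate["meanlog"]),
               tolerance = 1e-6)
  expect_equal(fit$sdlog, unname(ref$estimate["sdlog"]), tolerance = 1e-6)
  const <- fit_lognormal(rep(250, 20))
  expect_equal(const$sdlog, 0)
  expect_equal(const$meanlog, log(250))
  expect_error(fit_lognormal(1:5), "at least 10")
  expect_error(fit_lognormal(c(rep(1, 10), -1)), "positive")
  # consumption draws from a scenario are well described by a log-normal
  pred <- fixture_predators(seed = 2, n = 60)
  res <- run_scenario(scenario_config(1, abundance_scenario("N2"),
                                      n_sims = 500, seed = 4), pred)
  f <- fit_lognormal(res$draws[, "gummy_shark"])
  expect_equal(exp(f$meanlog + f$sdlog^2 / 2),
               mean(res$draws[, "gummy_shark"]), tolerance = 0.05)
})
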