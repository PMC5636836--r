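test_that("allometric routine metabolic rate follows the power law", {
  p <- metabolic_params()
  expect_equal(routine_mr(42, p), 214 * 42^0.79, tolerance = 1e-12)
  expect_equal(routine_mr(42, p), 4099.970319, tolerance = 1e-8)
  expect_equal(routine_mr(1, p), 214)  # unit mass returns the coefficient
  expect_equal(routine_mr(c(2, 8), p)[2] / routine_mr(c(2, 8), p)[1],
               4^0.79, tolerance = 1e-12)
  expect_error(routine_mr(0, p), "positive")
  expect_error(routine_mr(-1, p), "positive")
})

test_that("Q10 correction scales rates and composes across temperatures", {
  p <- metabolic_params()
  expect_equal(q10_adjust(100, p$ref_temp_c, p), 100)
  expect_equal(q10_adjust(100, 35, p, q10 = 1), 100)
  expect_equal(q10_adjust(1440.7, 16.7, p), 1110.641946, tolerance = 1e-8)
  # composition: 20 -> 15 -> 10 equals 20 -> 10 directly
  direct <- q10_adjust(500, 10, p)
  via15 <- q10_adjust(500, 15, p) * p$q10^((10 - 15) / 10)
  expect_equal(via15, direct, tolerance = 1e-12)
  # monotone increasing in temperature for q10 > 1
  temps <- seq(10, 24, by = 2)
  expect_true(all(diff(q10_adjust(1000, temps, p)) > 0))
  expect_error(q10_adjust(100, 15, p, q10 = 0), "positive")
})

test_that("oxycalorific conversion maps oxygen consumption to kJ per day", {
  p <- metabolic_params()
  expect_equal(mgo2_to_kj_per_day(4100, p), 1440.702782, tolerance = 1e-8)
  expect_equal(mgo2_to_kj_per_day(0, p), 0)
  expect_equal(mgo2_to_kj_per_day(68.3, p), 24)
})

test_that("growth and reproduction surcharges apply to the right individuals", {
  p <- metabolic_params()
  expect_equal(apply_costs(1000, "M", FALSE, FALSE, p), 1050)
  expect_equal(apply_costs(1000, "F", TRUE, TRUE, p), 1102.5)
  expect_equal(apply_costs(0, "M", FALSE, FALSE, p), 0)
  expect_error(apply_costs(1000, "M", FALSE, TRUE, p), "male or immature")
  expect_error(apply_costs(1000, "F", FALSE, TRUE, p), "male or immature")
})

test_that("individual period energy matches closed forms", {
  p <- metabolic_params()
  male42 <- data.frame(mass_kg = 42, sex = "M", mature = FALSE)
  flat20 <- temperature_regime(c(a = 20, b = 20, c = 20))
  expect_equal(individual_period_energy(male42, flat20, p),
               214 * 42^0.79 * 24 / 68.3 * 1.05 * 252, tolerance = 1e-12)
  # allometric scaling: doubling mass scales energy by 2^0.79
  both <- data.frame(mass_kg = c(42, 84), sex = "M", mature = FALSE)
  e <- individual_period_energy(both, temperature_regime(), p)
  expect_equal(e[2] / e[1], 2^0.79, tolerance = 1e-12)
  # spring daily component for a 42 kg male at q10 = 2.2
  spring_daily <- individual_period_energy(
    male42, temperature_regime(c(spring = 14), season_days = 252), p) / 252
  expect_equal(spring_daily, 942.5555204, tolerance = 1e-8)
})

test_that("population energy matches a naive per-individual per-day oracle", {
  p <- metabolic_params()
  pred <- fixture_predators(seed = 3, n = 40)
  regime <- temperature_regime()
  sel <- select_repro_females(pred, p, seed = 9)
  fast <- population_period_energy(pred, regime, p, n_population = 500,
                                   seed = 9)
  # oracle: loop over individuals, seasons and single days
  tot <- 0
  for (i in seq_len(nrow(pred))) {
    e_i <- 0
    for (s in seq_along(regime$season_temps_c)) {
      for (d in seq_len(regime$season_days[s])) {
        mr <- 214 * pred$mass_kg[i]^0.79
        kjd <- mr * 24 / 68.3 * 2.2^((regime$season_temps_c[[s]] - 20) / 10)
        kjd <- kjd * 1.05 * (if (sel[i]) 1.05 else 1)
        e_i <- e_i + kjd
      }
    }
    tot <- tot + e_i
  }
  expect_equal(fast, tot / nrow(pred) * 500, tolerance = 1e-9)
})

test_that("population period energy is linear in population size", {
  pred <- fixture_predators(seed = 4, n = 30)
  e1 <- population_period_energy(pred, n_population = 562)
  e2 <- population_period_energy(pred, n_population = 1124)
  expect_equal(e2, 2 * e1, tolerance = 1e-12)
  one <- data.frame(mass_kg = 42, sex = "M", mature = FALSE)
  expect_equal(population_period_energy(one, temperature_regime(),
                                        n_population = 1),
               individual_period_energy(one, temperature_regime()),
               tolerance = 1e-12)
})

test_that("seasonal daily rates bracket the rate at the overall mean", {
  pred <- fixture_predators(seed = 5)
  seas <- vapply(c(14.0, 19.1, 16.9),
                 function(t) population_mean_daily_mr(pred, t, seed = 2),
                 numeric(1))
  mid <- population_mean_daily_mr(pred, 16.7, seed = 2)
  expect_gt(mid, min(seas))
  expect_lt(mid, max(seas))
  # convexity of the Q10 exponential: the season-average rate exceeds the
  # rate at the season-average temperature
  expect_gt(mean(seas), population_mean_daily_mr(pred, mean(c(14, 19.1, 16.9)),
                                                 seed = 2))
  expect_error(population_mean_daily_mr(pred[0, ], 16.7), "empty")
})

test_that("fractional reproduction assignment equals its closed form", {
  p <- metabolic_params()
  pred <- data.frame(mass_kg = c(42, 42), sex = c("F", "M"),
                     mature = c(TRUE, FALSE))
  got <- population_mean_daily_mr(pred, 20, p, repro = "fractional")
  base <- 214 * 42^0.79 * 24 / 68.3 * 1.05
  expect_equal(got, base * (1 + (1 + 0.05 / 3)) / 2, tolerance = 1e-12)
})
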