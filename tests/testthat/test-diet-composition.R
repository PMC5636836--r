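test_that("frequency of occurrence counts distinct stomachs", {
  rec <- data.frame(
    shark_id = c(1:25, 1:100),
    species = c(rep("gummy_shark", 25), rep("teleosts", 100)))
  fo <- frequency_of_occurrence(rec, n_stomachs_total = 100)
  expect_equal(fo$variant, 1L)
  expect_equal(fo$fractions[["gummy_shark"]], 0.25)
  expect_equal(fo$fractions[["teleosts"]], 1)  # present in every stomach
  expect_false("eagle_ray" %in% names(fo$fractions))  # absent species: F = 0
  # duplicate records in one stomach count once
  dup <- rbind(rec, data.frame(shark_id = 1, species = "gummy_shark"))
  expect_equal(frequency_of_occurrence(dup, 100)$fractions[["gummy_shark"]],
               0.25)
  expect_error(frequency_of_occurrence(rec, 0), "positive")
  expect_error(frequency_of_occurrence(rec, 50), "smaller")
})

test_that("percent weight is the share of total partly digested weight", {
  rec <- data.frame(shark_id = c(1, 2), species = c("a", "b"),
                    partly_digested_weight_g = c(300, 100))
  pw <- percent_weight(rec)
  expect_equal(pw$fractions, c(a = 0.75, b = 0.25))
  one <- data.frame(shark_id = 1, species = "a",
                    partly_digested_weight_g = 500)
  expect_equal(percent_weight(one)$fractions, c(a = 1))
  expect_error(percent_weight(data.frame(shark_id = 1, species = "a",
                                         partly_digested_weight_g = 0)),
               "zero")
  # 10-species randomized table against a hand-summed oracle
  set.seed(10)
  big <- data.frame(shark_id = sample(1:30, 120, TRUE),
                    species = sample(letters[1:10], 120, TRUE),
                    partly_digested_weight_g = runif(120, 10, 5000))
  got <- percent_weight(big)$fractions
  for (s in letters[1:10]) {
    num <- 0
    for (i in seq_len(nrow(big))) {
      if (big$species[i] == s) num <- num + big$partly_digested_weight_g[i]
    }
    expect_equal(got[[s]], num / sum(big$partly_digested_weight_g),
                 tolerance = 1e-12)
  }
  expect_equal(sum(got), 1, tolerance = 1e-12)
})

test_that("count-times-average-weight composition matches brute force", {
  pp <- fixture_profiles()
  rec <- data.frame(shark_id = c(1, 2), species = c("eagle_ray", "teleosts"),
                    count = c(2L, 1L))
  # masses 9.1 and 0.8: products 18.2 and 0.8
  cw <- count_avg_weight(rec, pp)
  expect_equal(cw$fractions[["eagle_ray"]], 18.2 / 19.0, tolerance = 1e-12)
  expect_equal(sum(cw$fractions), 1, tolerance = 1e-12)
  # randomized 6-species table against an explicit loop oracle
  set.seed(11)
  sp6 <- c("gummy_shark", "school_shark", "dogshark", "eagle_ray",
           "teleosts", "cephalopods")
  big <- data.frame(shark_id = sample(1:40, 90, TRUE),
                    species = sample(sp6, 90, TRUE),
                    count = sample(1:4, 90, TRUE))
  got <- count_avg_weight(big, pp)$fractions
  mm <- setNames(pp$mean_mass_kg, pp$species)
  prod <- setNames(numeric(length(sp6)), sp6)
  for (i in seq_len(nrow(big))) {
    prod[big$species[i]] <- prod[big$species[i]] +
      big$count[i] * mm[[big$species[i]]]
  }
  expect_equal(got[sp6], prod / sum(prod), tolerance = 1e-12)
  expect_error(
    count_avg_weight(data.frame(shark_id = 1, species = "kraken", count = 1),
                     pp),
    "kraken")
})

test_that("equal mean masses reduce variant 3 to percent-number", {
  pp <- fixture_profiles()
  pp$mean_mass_kg[] <- 2.5
  rec <- data.frame(shark_id = c(1, 1, 2), species = c("gummy_shark",
                                                       "teleosts",
                                                       "gummy_shark"),
                    count = c(3L, 1L, 1L))
  cw <- count_avg_weight(rec, pp)
  expect_equal(cw$fractions[["gummy_shark"]], 4 / 5, tolerance = 1e-12)
})

test_that("compositional variants are invariant to order and record splits", {
  rec <- toy_records()
  perm <- rec[sample(nrow(rec)), ]
  expect_equal(percent_weight(perm)$fractions[names(
    percent_weight(rec)$fractions)], percent_weight(rec)$fractions)
  # split one record into two with the same totals
  split1 <- rec
  split1$partly_digested_weight_g[1] <- 700
  split1$count[1] <- 1L
  extra <- rec[1, ]
  extra$partly_digested_weight_g <- 800
  extra$count <- 1L
  split1 <- rbind(split1, extra)
  expect_equal(percent_weight(split1)$fractions, percent_weight(rec)$fractions,
               tolerance = 1e-12)
  pp <- fixture_profiles()
  expect_equal(count_avg_weight(split1, pp)$fractions,
               count_avg_weight(rec, pp)$fractions, tolerance = 1e-12)
})

test_that("the diet composition constructor enforces the simplex constraint", {
  expect_error(diet_composition(2, c(a = 0.6, b = 0.3)), "sum to 1")
  expect_silent(diet_composition(2, c(a = 0.6, b = 0.4)))
  expect_silent(diet_composition(1, c(a = 0.6, b = 0.3)))  # FO need not sum
})

test_that("stomach bootstrap preserves the simplex per replicate", {
  st <- fixture_stomachs(seed = 6, n_stomachs = 80)
  set.seed(20)
  for (i in 1:20) {
    bs <- ectopred:::bootstrap_stomachs(st)
    expect_equal(sum(percent_weight(bs)$fractions), 1, tolerance = 1e-9)
    expect_equal(sum(count_avg_weight(bs, fixture_profiles())$fractions), 1,
                 tolerance = 1e-9)
  }
})
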