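# The 2-female x 3-male fixture has 9 equally likely random assignments;
# exact null probabilities are enumerated in helper-fixtures.R.

test_that("breeding randomization is uniform over the candidate pool", {
  fx <- perm_fixture()
  # forced assignment: single candidate -> permuted set equals observed set
  ds1 <- fx$dataset
  ds1$membership <- ds1$membership[!ds1$membership$individual_id %in%
                                     c("MA", "MB"), ]
  dy1 <- data.frame(attempt_id = "A1", female_id = "FA", male_id = "MC")
  set.seed(1)
  expect_equal(randomize_breeding_dyads(dy1, ds1, fx$A)$male_id, "MC")

  # frequency check: female with 1 sire among 3 candidates, uniform 1/3 each
  set.seed(42)
  draws <- table(replicate(6000, randomize_breeding_dyads(
    fx$dyads[1, ], fx$dataset, fx$A)$male_id))
  expect_true(all(abs(draws / 6000 - 1 / 3) < 3 * sqrt(2 / 9 / 6000)))

  # female with 2 sires among 3 candidates: unordered pairs uniform 1/3 each
  dy2 <- data.frame(attempt_id = "A1", female_id = c("FA", "FA"),
                    male_id = c("MA", "MB"))
  set.seed(43)
  pairs <- replicate(6000, paste(sort(randomize_breeding_dyads(
    dy2, fx$dataset, fx$A)$male_id), collapse = "+"))
  tab <- table(pairs) / 6000
  expect_setequal(names(tab), c("MA+MB", "MA+MC", "MB+MC"))
  expect_true(all(abs(tab - 1 / 3) < 3 * sqrt(2 / 9 / 6000)))

  # candidate pool smaller than multiplicity: rows flagged and excluded
  ds2 <- fx$dataset
  ds2$membership <- ds2$membership[ds2$membership$individual_id != "MC", ]
  dy3 <- data.frame(attempt_id = "A1", female_id = c("FA", "FA", "FA"),
                    male_id = c("MA", "MB", "MC"))
  expect_warning(out <- randomize_breeding_dyads(dy3, ds2, fx$A),
                 "pool too small")
  expect_equal(nrow(out), 0L)
})

test_that("Monte Carlo p matches the exact enumeration on the small fixture", {
  fx <- perm_fixture()
  # exact: null mean = r(FA, x)/2 over x in {MA: 0.5, MB: 0.25, MC: 0};
  # observed mean 0.125 -> P(null <= obs) = 2/3
  n_perms <- 20000
  pt <- permutation_test(fx$dyads, fx$dataset, fx$A, type = "breeding",
                         n_perms = n_perms, seed = 5)
  expect_equal(pt$observed_mean, 0.125)
  expect_equal(pt$n_dyads, 2L)
  q <- 2 / 3
  expect_lt(abs(pt$p_one_tailed - q), 3 * sqrt(q * (1 - q) / n_perms))
  # null-mean average converges to the analytic expectation:
  # E[null mean] = (mean r(FA, pool) + mean r(FB, pool)) / 2 = 0.125
  expect_lt(abs(mean(pt$null_means) - 0.125), 0.005)
})

test_that("Monte Carlo p-value conventions: add-one, ties, extremes", {
  fx <- perm_fixture()
  # degenerate guard event (1 guard, 1 female): null equals observed, p = 1
  gdy <- data.frame(attempt_id = "A1", male_id = "MA", female_id = "FA")
  pt <- permutation_test(gdy, fx$dataset, fx$A, type = "guard",
                         n_perms = 99, seed = 1)
  expect_equal(pt$p_one_tailed, 1)

  # observed below every achievable null: p = 1 / (n_perms + 1)
  # (FB's observed male is unrelated, but every candidate in a pool of
  # relatives has r > 0)
  ped <- validate_pedigree(data.frame(
    id = c("Q", "R", "S1", "S2", "FX", "MZ"),
    dam = c(NA, NA, "Q", "Q", "Q", NA),
    sire = c(NA, NA, "R", "R", "R", NA),
    sex = c("F", "M", "M", "M", "F", "M"),
    birth_date = c("1999-01-01", "1999-01-01", rep("2000-01-01", 4))))
  A <- relatedness_matrix(ped)
  ds <- suppressWarnings(study_dataset(
    ped,
    membership = data.frame(group_id = "G", attempt_id = "A",
                            individual_id = c("FX", "S1", "S2")),
    attempts = data.frame(attempt_id = "A", group_id = "G",
                          oestrus_start_date = "2003-06-01"),
    parentage = data.frame(offspring_id = "PP", attempt_id = "A",
                           dam_id = "FX", sire_id = "MZ",
                           dam_confidence = 1, sire_confidence = 1),
    guards = data.frame(attempt_id = "A", guard_id = "S1", female_id = "FX",
                        n_days_guarding = 1L),
    outcomes = data.frame(individual_id = "PP", age_days = NA_integer_,
                          body_mass_g = NA_real_, survived_to_1yr = NA),
    quiet = TRUE))
  dy <- data.frame(attempt_id = "A", female_id = "FX", male_id = "MZ")
  pt2 <- permutation_test(dy, ds, A, type = "breeding", n_perms = 9999,
                          seed = 2)
  expect_equal(pt2$p_one_tailed, 1e-4)

  # empty dyad set errors
  expect_error(permutation_test(dy[0, ], ds, A, "breeding"), "empty")
})

test_that("guard reshuffle preserves degrees and never duplicates an edge", {
  fx <- perm_fixture()
  # 2 guards x 2 females, all degree 1: the two perfect matchings are
  # equally likely
  gdy <- data.frame(attempt_id = "A1",
                    male_id = c("MA", "MB"), female_id = c("FA", "FB"))
  set.seed(9)
  same <- replicate(4000, {
    out <- randomize_guard_dyads(gdy, fx$dataset, fx$A)
    identical(out$female_id, gdy$female_id)
  })
  expect_lt(abs(mean(same) - 0.5), 3 * sqrt(0.25 / 4000))

  # a guard of 2 females among 3 guarded females never gets the same
  # female twice, and per-male / per-female edge counts are preserved
  gdy2 <- data.frame(attempt_id = "A1",
                     male_id = c("MA", "MA", "MB", "MC"),
                     female_id = c("FA", "FB", "FB", "FA"))
  set.seed(10)
  for (i in 1:200) {
    out <- randomize_guard_dyads(gdy2, fx$dataset, fx$A)
    expect_false(anyDuplicated(paste(out$male_id, out$female_id)) > 0)
    expect_equal(table(out$male_id), table(gdy2$male_id))
    expect_equal(table(out$female_id), table(gdy2$female_id))
  }
})

test_that("permutation tests are reproducible and independent across events", {
  fx <- perm_fixture()
  p1 <- permutation_test(fx$dyads, fx$dataset, fx$A, "breeding",
                         n_perms = 500, seed = 77)
  p2 <- permutation_test(fx$dyads, fx$dataset, fx$A, "breeding",
                         n_perms = 500, seed = 77)
  expect_identical(p1$null_means, p2$null_means)
  expect_identical(p1$p_one_tailed, p2$p_one_tailed)
  p3 <- permutation_test(fx$dyads, fx$dataset, fx$A, "breeding",
                         n_perms = 500, seed = 78)
  expect_false(identical(p1$null_means, p3$null_means))
})
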