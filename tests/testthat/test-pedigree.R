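test_that("validate_pedigree orders parents before offspring and flags errors", {
  ped <- validate_pedigree(data.frame(
    id = c("C", "A", "B"), dam = c("A", NA, NA), sire = c("B", NA, NA),
    sex = c("F", "F", "M")))
  expect_s3_class(ped, "pedigree")
  expect_lt(max(match(c("A", "B"), ped$id)), match("C", ped$id))

  # duplicate id
  expect_error(validate_pedigree(data.frame(
    id = c("A", "A"), dam = NA, sire = NA)), "duplicate")

  # self-ancestry and longer cycles
  expect_error(validate_pedigree(data.frame(
    id = "A", dam = "A", sire = NA)), "cycle")
  expect_error(validate_pedigree(data.frame(
    id = c("A", "B"), dam = c("B", "A"), sire = c(NA, NA))), "cycle")

  # a 9-generation chain validates with all 10 members in order
  n <- 10
  chain <- data.frame(id = paste0("I", 1:n),
                      dam = c(NA, paste0("I", 1:(n - 1))),
                      sire = NA, sex = "F")
  out <- validate_pedigree(chain)
  expect_equal(out$id, paste0("I", 1:n))

  # dangling parent promoted to founder with a warning
  expect_warning(
    ped2 <- validate_pedigree(data.frame(
      id = c("K", "L"), dam = c("ZZ", "ZZ"), sire = c(NA, NA))),
    "dangling")
  expect_true("ZZ" %in% ped2$id)
  # the shared unknown dam makes K and L maternal half sibs
  expect_equal(relatedness(relatedness_matrix(ped2), "K", "L"), 0.25)
})

test_that("kinship recursion reproduces textbook values and F = 0.375 pedigree", {
  ped <- toy_pedigree()
  A <- relatedness_matrix(ped)
  Ftab <- inbreeding(ped)
  Fv <- setNames(Ftab$F, Ftab$individual_id)

  expect_equal(relatedness(A, "A", "C"), 0.5)  # parent-offspring
  expect_equal(relatedness(A, "C", "D"), 0.5)  # full sibs
  expect_equal(relatedness(A, "A", "B"), 0)    # founders
  expect_equal(unname(Fv["E"]), 0.25)          # full-sib mating
  expect_equal(unname(Fv["X"]), 0.375)         # the constructed maximum
  expect_equal(unname(Fv[c("A", "B", "C", "D")]), rep(0, 4))

  # half sibs r = 0.25; grandparent-grandchild r = 0.25
  hs <- validate_pedigree(data.frame(
    id = c("m", "s1", "s2", "k1", "k2", "g"),
    dam = c(NA, NA, NA, "m", "m", "k1"),
    sire = c(NA, NA, NA, "s1", "s2", "s2"),
    sex = c("F", "M", "M", "F", "M", "F")))
  Ah <- relatedness_matrix(hs)
  expect_equal(relatedness(Ah, "k1", "k2"), 0.25)
  expect_equal(relatedness(Ah, "m", "g"), 0.25)

  # unknown single parent: missing side is a unique founder, F = 0
  up <- validate_pedigree(data.frame(
    id = c("d", "x"), dam = c(NA, "d"), sire = c(NA, NA), sex = c("F", "M")))
  expect_equal(inbreeding(up)$F, c(0, 0))
  expect_false(inbreeding(up)$parents_known[2])
})

test_that("relatedness matrix invariants hold on random pedigrees", {
  for (s in 1:3) {
    ped <- suppressWarnings(random_pedigree(seed = s))
    A <- relatedness_matrix(ped)
    f <- kinship_matrix(ped)
    expect_true(isSymmetric(unclass(A)))
    expect_true(all(A >= 0 & A <= 2))
    # diagonal is 1 + F with F = f(dam, sire)
    Ftab <- inbreeding(ped, f)
    expect_equal(unname(diag(A)), 1 + Ftab$F)
    for (i in which(!is.na(ped$dam_idx) & !is.na(ped$sire_idx)))
      expect_equal(A[i, i] - 1, f[ped$dam_idx[i], ped$sire_idx[i]])
    # removing a childless individual leaves all other entries unchanged
    childless <- setdiff(ped$id, c(ped$dam, ped$sire))[1]
    ped2 <- validate_pedigree(ped[ped$id != childless,
                                  c("id", "dam", "sire", "sex")])
    A2 <- relatedness_matrix(ped2)
    expect_equal(A2[ped2$id, ped2$id], A[ped2$id, ped2$id],
                 tolerance = 1e-12)
  }
})

test_that("gene dropping agrees with the kinship recursion", {
  ped <- toy_pedigree()
  gd <- gene_drop(ped, n_replicates = 50000, seed = 99)
  # founders: F estimate exactly 0; textbook pairs near closed form
  expect_equal(unname(gd$F["A"]), 0)
  se_F <- sqrt(0.25 * 0.75 / 50000)
  expect_lt(abs(gd$F[["E"]] - 0.25), 3 * se_F)
  expect_lt(abs(gd$r["A", "C"] - 0.5), 4 * 2 * sqrt(0.25 * 0.75 / 50000))
  expect_lt(abs(gd$F[["X"]] - 0.375), 3 * sqrt(0.375 * 0.625 / 50000))

  # reproducible for a fixed seed
  gd2 <- gene_drop(ped, n_replicates = 1000, seed = 7)
  gd3 <- gene_drop(ped, n_replicates = 1000, seed = 7)
  expect_identical(gd2, gd3)

  # full-matrix agreement on a random pedigree within 4 Monte Carlo SEs
  rp <- suppressWarnings(random_pedigree(n_founders = 10, n_gen = 4,
                                         per_gen = 10, seed = 11))
  n_rep <- 20000
  gdr <- gene_drop(rp, n_replicates = n_rep, seed = 12)
  f <- kinship_matrix(rp)
  se <- sqrt(pmax(f * (1 - f), 1e-12) / n_rep)
  dev <- abs(gdr$kinship - f) / se
  expect_lt(max(dev[upper.tri(dev)]), 4)
})

test_that("pedigree CSV round-trips and writers emit long/table formats", {
  ped <- toy_pedigree()
  tmp <- withr::local_tempdir()
  pp <- file.path(tmp, "ped.csv")
  utils::write.csv(ped[, c("id", "dam", "sire", "sex", "birth_date",
                           "natal_group")],
                   pp, row.names = FALSE, na = "")
  ped2 <- read_pedigree_csv(pp)
  expect_equal(kinship_matrix(ped2)[ped$id, ped$id],
               kinship_matrix(ped)[ped$id, ped$id])

  A <- relatedness_matrix(ped)
  rl <- file.path(tmp, "rel.csv")
  write_relatedness_long(A, rl)
  long <- utils::read.csv(rl)
  expect_equal(nrow(long), nrow(A) * (nrow(A) + 1) / 2)
  expect_equal(long$r[long$id1 == "A" & long$id2 == "C"], 0.5)

  fi <- file.path(tmp, "inb.csv")
  write_inbreeding(ped, fi)
  itab <- utils::read.csv(fi)
  expect_equal(itab$F[itab$id == "X"], 0.375)
})
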