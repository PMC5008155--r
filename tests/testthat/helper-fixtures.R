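# Fixtures are built in code so every expected value can be hand-enumerated.

# Classic verification pedigree: A,B founders; C,D full-sib offspring of A x B;
# E = offspring of D x C; X = offspring of E x C. F_X = f(E, C) = 0.375.
toy_pedigree <- function() {
  validate_pedigree(data.frame(
    id   = c("A", "B", "C", "D", "E", "X"),
    dam  = c(NA, NA, "A", "A", "D", "E"),
    sire = c(NA, NA, "B", "B", "C", "C"),
    sex  = c("F", "M", "M", "F", "F", "M"),
    stringsAsFactors = FALSE))
}

# Random multi-generation pedigree for property tests.
random_pedigree <- function(n_founders = 10, n_gen = 4, per_gen = 10,
                            seed = 1) {
  set.seed(seed)
  id <- paste0("FND", seq_len(n_founders))
  dam <- sire <- rep(NA_character_, n_founders)
  sex <- rep(c("F", "M"), length.out = n_founders)
  for (g in seq_len(n_gen)) {
    fe <- id[sex == "F"]
    ma <- id[sex == "M"]
    for (k in seq_len(per_gen)) {
      id <- c(id, sprintf("G%d_%d", g, k))
      dam <- c(dam, sample(fe, 1))
      sire <- c(sire, sample(ma, 1))
      sex <- c(sex, sample(c("F", "M"), 1))
    }
  }
  validate_pedigree(data.frame(id, dam, sire, sex, stringsAsFactors = FALSE))
}

# Hand-enumerable study dataset: one social group (G1) with two observed
# attempts, one neighbouring group (G2), known relatedness structure.
# Expected filter outcomes are worked out by hand in the tests.
toy_dataset <- function(quiet = TRUE) {
  ped <- data.frame(
    id   = c("GM1", "GS1", "GM2", "GS2",
             "F1", "M1", "M3", "F3", "M2", "M4", "EG1",
             "F2", "EGF", "YM",
             "P1", "P2", "P4", "P3", "P5"),
    dam  = c(NA, NA, NA, NA,
             "GM1", "GM1", "GM1", "GM2", "GM2", "GM2", "GM2",
             NA, NA, "GM1",
             "F1", "F3", "F2", "F1", NA),
    sire = c(NA, NA, NA, NA,
             "GS1", "GS1", "GS1", "GS2", "GS2", "GS2", "GS2",
             NA, NA, "GS2",
             "M2", "M2", "M1", "EG1", NA),
    sex  = c("F", "M", "F", "M",
             "F", "M", "M", "F", "M", "M", "M",
             "F", "F", "M",
             "M", "F", "F", "M", "M"),
    birth_date = c(rep("2000-01-01", 4),
                   rep("2001-01-01", 7),
                   "2000-06-01", "2000-06-01", "2002-12-01",
                   "2003-07-31", "2003-07-31", "2003-07-31", "2003-10-31",
                   "2003-07-31"),
    natal_group = c(rep(NA, 4),
                    "G1", "G1", "G1", "G1", "G1", "G1", "G2",
                    NA, NA, "G1",
                    "G1", "G1", "G1", "G1", "G1"),
    stringsAsFactors = FALSE)

  membership <- data.frame(
    group_id = c(rep("G1", 8), rep("G1", 5), rep("G2", 2)),
    attempt_id = c(rep("A1", 8), rep("A2", 5), rep("A3", 2)),
    individual_id = c("F1", "F2", "F3", "M1", "M2", "M3", "M4", "YM",
                      "F1", "F3", "M1", "M2", "M4",
                      "EG1", "EGF"),
    stringsAsFactors = FALSE)

  attempts <- data.frame(
    attempt_id = c("A1", "A2", "A3"),
    group_id = c("G1", "G1", "G2"),
    oestrus_start_date = c("2003-06-01", "2003-09-01", "2003-06-01"),
    birth_date = c("2003-07-31", "2003-10-31", "2003-07-31"),
    rainfall_30d = c(2.0, 3.0, 2.0),
    group_size_adults = c(7L, 5L, 2L),
    n_pups_born = c(3L, 1L, 0L),
    stringsAsFactors = FALSE)

  # parent assignments: the 2001 cohort (attempt unknown) plus the pups
  parentage <- data.frame(
    offspring_id = c("F1", "M1", "M3", "F3", "M2", "M4", "EG1", "YM",
                     "P1", "P2", "P4", "P3"),
    attempt_id = c(rep(NA_character_, 8), "A1", "A1", "A1", "A2"),
    dam_id  = c("GM1", "GM1", "GM1", "GM2", "GM2", "GM2", "GM2", "GM1",
                "F1", "F3", "F2", "F1"),
    sire_id = c("GS1", "GS1", "GS1", "GS2", "GS2", "GS2", "GS2", "GS2",
                "M2", "M2", "M1", "EG1"),
    dam_confidence = 1, sire_confidence = 1,
    stringsAsFactors = FALSE)

  guards <- data.frame(
    attempt_id = c("A1", "A1", "A2"),
    guard_id = c("M1", "M2", "M4"),
    female_id = c("F1", "F3", "F1"),
    n_days_guarding = c(3L, 2L, 1L),
    stringsAsFactors = FALSE)

  outcomes <- data.frame(
    individual_id = c("P1", "P1", "P2", "P3", "P4", "P5"),
    age_days = c(360L, 340L, 355L, 365L, NA, 358L),
    body_mass_g = c(1200, 1100, 1150, 1300, NA, 1000),
    survived_to_1yr = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)

  ds <- suppressWarnings(study_dataset(validate_pedigree(ped), membership,
                                       attempts, parentage, guards, outcomes,
                                       quiet = quiet))
  list(dataset = ds, A = relatedness_matrix(ds$pedigree))
}

# 2-female x 3-male single-attempt fixture with non-trivial relatedness:
# FA is a full sib of MA (r = 0.5) and an aunt of MB (r = 0.25);
# FB and MC are unrelated founders. Observed dyads: (FA, MB), (FB, MC).
# Under random assignment of one male per female (3 x 3 = 9 equally likely
# configurations) the null mean relatedness is r(FA, x) / 2, so the exact
# one-sided probability P(null <= observed = 0.125) is 2/3.
perm_fixture <- function() {
  ped <- data.frame(
    id   = c("PF", "PM", "FA", "MA", "MB", "FB", "MC", "Q"),
    dam  = c(NA, NA, "PF", "PF", "Q", NA, NA, NA),
    sire = c(NA, NA, "PM", "PM", "MA", NA, NA, NA),
    sex  = c("F", "M", "F", "M", "M", "F", "M", "F"),
    birth_date = c(rep("2000-01-01", 2), "2001-01-01", "2001-01-01",
                   "2001-06-01", "2001-01-01", "2001-01-01", "2000-01-01"),
    natal_group = c(NA, NA, "G1", "G1", "G1", NA, NA, NA),
    stringsAsFactors = FALSE)
  membership <- data.frame(
    group_id = "G1", attempt_id = "A1",
    individual_id = c("FA", "FB", "MA", "MB", "MC"),
    stringsAsFactors = FALSE)
  attempts <- data.frame(
    attempt_id = "A1", group_id = "G1", oestrus_start_date = "2003-06-01",
    birth_date = "2003-07-31", rainfall_30d = 2, group_size_adults = 5L,
    n_pups_born = 2L, stringsAsFactors = FALSE)
  parentage <- data.frame(
    offspring_id = c("X1", "X2"), attempt_id = "A1",
    dam_id = c("FA", "FB"), sire_id = c("MB", "MC"),
    dam_confidence = 1, sire_confidence = 1, stringsAsFactors = FALSE)
  guards <- data.frame(attempt_id = "A1", guard_id = "MA", female_id = "FA",
                       n_days_guarding = 1L, stringsAsFactors = FALSE)
  outcomes <- data.frame(individual_id = "X1", age_days = NA_integer_,
                         body_mass_g = NA_real_, survived_to_1yr = TRUE,
                         stringsAsFactors = FALSE)
  ds <- suppressWarnings(study_dataset(validate_pedigree(ped), membership,
                                       attempts, parentage, guards, outcomes,
                                       quiet = TRUE))
  list(dataset = ds, A = relatedness_matrix(ds$pedigree),
       dyads = data.frame(attempt_id = "A1",
                          female_id = c("FA", "FB"),
                          male_id = c("MB", "MC"),
                          stringsAsFactors = FALSE))
}
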