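#' Assemble a study dataset from its component tables
#'
#' Bundles the five behavioural/life-history tables and the pedigree into a
#' cross-validated `study_dataset`. Derived columns are added to the
#' membership table at assembly time: `age_days` (age at the attempt's oestrus
#' start, from the pedigree birth date), `age_rank` (1 = oldest among same-sex
#' members of the attempt with known age) and, if absent, `sex` and `is_natal`
#' (recorded natal group equals the attempt's group).
#'
#' @param pedigree a `pedigree` from [validate_pedigree()]
#' @param membership data.frame: `group_id, attempt_id, individual_id`
#'   (+ optional `sex`, `is_natal`)
#' @param attempts data.frame: `attempt_id, group_id, oestrus_start_date,
#'   birth_date, rainfall_30d, group_size_adults, n_pups_born`
#' @param parentage data.frame: `offspring_id, attempt_id, dam_id, sire_id,
#'   dam_confidence, sire_confidence`
#' @param guards data.frame: `attempt_id, guard_id, female_id, n_days_guarding`
#' @param outcomes data.frame: `individual_id, age_days, body_mass_g,
#'   survived_to_1yr`
#' @param quiet suppress the per-table row-count log
#' @return a `study_dataset` (list of the six tables)
#' @export
study_dataset <- function(pedigree, membership, attempts, parentage, guards,
                          outcomes, quiet = FALSE) {
  if (!is_pedigree(pedigree)) pedigree <- validate_pedigree(pedigree)
  need_cols(membership, c("group_id", "attempt_id", "individual_id"), "membership")
  need_cols(attempts, c("attempt_id", "group_id", "oestrus_start_date"), "attempts")
  need_cols(parentage, c("offspring_id", "attempt_id", "dam_id", "sire_id",
                         "dam_confidence", "sire_confidence"), "parentage")
  need_cols(guards, c("attempt_id", "guard_id", "female_id", "n_days_guarding"),
            "guards")
  need_cols(outcomes, c("individual_id", "age_days", "body_mass_g",
                        "survived_to_1yr"), "outcomes")
  if (anyDuplicated(attempts$attempt_id))
    stop("duplicate attempt_id in attempts table")

  for (col in c("oestrus_start_date", "birth_date"))
    if (!is.null(attempts[[col]])) attempts[[col]] <- as.Date(attempts[[col]])
  if (is.null(attempts$birth_date)) attempts$birth_date <- as.Date(NA)
  if (is.null(attempts$rainfall_30d)) attempts$rainfall_30d <- NA_real_
  if (is.null(attempts$n_pups_born)) attempts$n_pups_born <- NA_integer_

  # referential integrity (warnings, not errors: field tables often contain
  # ids that never entered the pedigree)
  known <- pedigree$id
  orphans <- unique(c(setdiff(membership$individual_id, known),
                      setdiff(parentage$offspring_id, known),
                      setdiff(c(guards$guard_id, guards$female_id), known)))
  if (length(orphans))
    warning("id(s) absent from pedigree: ", paste(orphans, collapse = ", "))
  for (nm in c("membership", "parentage", "guards")) {
    tab <- get(nm)
    bad <- setdiff(unique(stats::na.omit(tab$attempt_id)), attempts$attempt_id)
    if (length(bad))
      warning(nm, " references unknown attempt_id(s): ",
              paste(bad, collapse = ", "))
  }
  if (anyDuplicated(guards[, c("attempt_id", "guard_id", "female_id")]))
    warning("duplicate (attempt, guard, female) rows in guards table")

  membership <- derive_membership(membership, attempts, pedigree)

  if (is.null(attempts$group_size_adults) || all(is.na(attempts$group_size_adults))) {
    n_ad <- tapply(!is.na(membership$age_days) & membership$age_days > 365,
                   membership$attempt_id, sum)
    attempts$group_size_adults <- as.integer(n_ad[as.character(attempts$attempt_id)])
  }

  ds <- structure(list(pedigree = pedigree, membership = membership,
                       attempts = attempts, parentage = parentage,
                       guards = guards, outcomes = outcomes),
                  class = "study_dataset")
  if (!quiet)
    message("study_dataset: ",
            paste(sprintf("%s=%d", names(ds),
                          vapply(ds, nrow, 0L)), collapse = ", "))
  ds
}

derive_membership <- function(membership, attempts, pedigree) {
  m <- as.data.frame(membership, stringsAsFactors = FALSE)
  pidx <- match(m$individual_id, pedigree$id)
  if (is.null(m$sex)) m$sex <- pedigree$sex[pidx] else m$sex <- normalize_sex(m$sex)
  oest <- attempts$oestrus_start_date[match(m$attempt_id, attempts$attempt_id)]
  m$age_days <- as.integer(oest - pedigree$birth_date[pidx])
  if (is.null(m$is_natal)) {
    natal <- pedigree$natal_group[pidx]
    m$is_natal <- !is.na(natal) & natal == m$group_id
  } else {
    m$is_natal <- as.logical(m$is_natal)
  }
  # age rank: 1 = oldest same-sex member of the attempt with known age
  m$age_rank <- NA_integer_
  key <- interaction(m$attempt_id, m$sex, drop = TRUE)
  for (g in split(seq_len(nrow(m)), key)) {
    a <- m$age_days[g]
    kn <- !is.na(a)
    m$age_rank[g[kn]] <- as.integer(rank(-a[kn], ties.method = "first"))
  }
  m
}

#' Read the canonical study tables from CSV files
#'
#' Readers auto-detect comma vs tab delimiters and tolerate a UTF-8 BOM.
#' A column map (per table, `list(canonical = "source_header")`) adapts
#' externally deposited files whose headers differ from the canonical schema.
#'
#' @param paths named list/vector with elements `pedigree`, `membership`,
#'   `attempts`, `parentage`, `guards`, `outcomes`
#' @param column_map optional named list (same table names) of column maps
#' @param quiet suppress the row-count log
#' @return a `study_dataset`
#' @export
read_study_tables <- function(paths, column_map = NULL, quiet = FALSE) {
  need <- c("pedigree", "membership", "attempts", "parentage", "guards", "outcomes")
  miss <- setdiff(need, names(paths))
  if (length(miss)) stop("paths must name: ", paste(miss, collapse = ", "))
  raw <- lapply(stats::setNames(need, need), function(nm) {
    apply_column_map(read_delim_auto(paths[[nm]]), column_map[[nm]])
  })
  study_dataset(validate_pedigree(raw$pedigree), raw$membership, raw$attempts,
                raw$parentage, raw$guards, raw$outcomes, quiet = quiet)
}

#' Write a study dataset as canonical CSV tables
#'
#' @param dataset a `study_dataset`
#' @param dir output directory (created if needed)
#' @return named vector of file paths, invisibly
#' @export
write_study_tables <- function(dataset, dir) {
  stopifnot(inherits(dataset, "study_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  ped <- dataset$pedigree[, c("id", "dam", "sire", "sex", "birth_date", "natal_group")]
  tabs <- list(
    pedigree = ped,
    membership = dataset$membership[, c("group_id", "attempt_id", "individual_id",
                                        "sex", "is_natal")],
    attempts = dataset$attempts[, c("attempt_id", "group_id", "oestrus_start_date",
                                    "birth_date", "rainfall_30d",
                                    "group_size_adults", "n_pups_born")],
    parentage = dataset$parentage[, c("offspring_id", "attempt_id", "dam_id",
                                      "sire_id", "dam_confidence",
                                      "sire_confidence")],
    guards = dataset$guards[, c("attempt_id", "guard_id", "female_id",
                                "n_days_guarding")],
    outcomes = dataset$outcomes[, c("individual_id", "age_days", "body_mass_g",
                                    "survived_to_1yr")])
  for (nm in names(tabs)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tabs[[nm]], p, row.names = FALSE, quote = FALSE, na = "")
    paths[nm] <- p
  }
  invisible(paths)
}

#' Adult candidates of one sex for a breeding attempt
#'
#' Members of the attempt's group aged > 1 year (age_days > 365 at the oestrus
#' start) of the requested sex. Members with unknown age are excluded.
#'
#' @param dataset a `study_dataset`
#' @param attempt_id attempt identifier
#' @param sex `"F"` or `"M"`
#' @return character vector of individual ids (sorted, deterministic)
#' @export
candidate_adults <- function(dataset, attempt_id, sex = c("M", "F")) {
  sex <- match.arg(sex)
  if (!attempt_id %in% dataset$attempts$attempt_id)
    stop("unknown attempt_id: ", attempt_id)
  m <- dataset$membership
  sel <- m$attempt_id == attempt_id & m$sex %in% sex &
    !is.na(m$age_days) & m$age_days > 365
  sort(unique(m$individual_id[sel]))
}

# ids whose own parents are confidently assigned (both confidences >= 0.8)
assigned_parents_ids <- function(dataset, threshold = 0.8) {
  p <- dataset$parentage
  ok <- !is.na(p$dam_id) & !is.na(p$sire_id) &
    !is.na(p$dam_confidence) & p$dam_confidence >= threshold &
    !is.na(p$sire_confidence) & p$sire_confidence >= threshold
  unique(p$offspring_id[ok])
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("study_dataset\n")
  for (nm in names(x))
    cat(sprintf("  %-10s %6d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}
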