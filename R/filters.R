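#' @name cohort_filters
#' @title Inclusion/exclusion filters with per-criterion accounting
#'
#' @description Each analysis applies a fixed set of inclusion criteria to its
#' candidate rows. Filters return both the retained rows and a `filter_report`
#' recording, for every criterion, how many input rows pass it, plus the number
#' retained (the conjunction of all criteria). For attribution purposes each
#' dropped row is charged to the first criterion it fails, in the stated
#' criterion order; retention itself does not depend on that order.
NULL

make_filter_report <- function(analysis_name, crit, retained_keys) {
  stopifnot(is.data.frame(crit))
  cm <- as.matrix(crit)
  cm[is.na(cm)] <- FALSE
  keep <- rowSums(!cm) == 0L
  first_fail <- if (nrow(cm)) apply(cm, 1L, function(z) which(!z)[1])
                else integer(0)
  dropped_by <- table(factor(colnames(cm)[first_fail[!keep]], levels = colnames(cm)))
  structure(list(analysis_name = analysis_name,
                 n_input = nrow(cm),
                 per_criterion_pass_counts = colSums(cm),
                 n_retained = sum(keep),
                 dropped_by = c(dropped_by),
                 retained_keys = retained_keys),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report [%s]: %d input, %d retained\n",
              x$analysis_name, x$n_input, x$n_retained))
  for (nm in names(x$per_criterion_pass_counts))
    cat(sprintf("  %-28s pass %d/%d (drop attribution %d)\n", nm,
                x$per_criterion_pass_counts[[nm]], x$n_input,
                x$dropped_by[[nm]]))
  invisible(x)
}

# attempts where every adult (age > 365 d) of the given sex(es) was born in
# the group; attempts with no such adults are excluded
natal_attempts <- function(dataset, sexes) {
  m <- dataset$membership
  ad <- m[!is.na(m$age_days) & m$age_days > 365 & m$sex %in% sexes, , drop = FALSE]
  ok <- tapply(ad$is_natal, ad$attempt_id, function(z) all(!is.na(z) & z))
  names(ok)[!is.na(ok) & ok]
}

in_roster <- function(dataset, attempt_id, id) {
  m <- dataset$membership
  paste(attempt_id, id) %in% paste(m$attempt_id, m$individual_id)
}

#' Breeding-pair inclusion filter
#'
#' Builds the observed mother-sire dyads (unique (mother, sire, attempt)
#' triples from confidently assigned parentage; several pups of one pair in
#' one attempt count once) and applies the inclusion criteria:
#' (1) the mother has both of her own parents confidently assigned;
#' (2) at least 80\% of candidate fathers (adult males of the group at the
#' attempt, or all assigned sires population-wide, see `candidate_scope`)
#' have confidently assigned parents;
#' (3) the sire belongs to the mother's group at the attempt (within-group
#' mating).
#' With `natal_only = TRUE` the input is first limited to attempts where every
#' adult of both sexes is natal to the group.
#'
#' @param dataset a `study_dataset`
#' @param a relatedness matrix over the pedigree
#' @param natal_only restrict to all-natal attempts first
#' @param candidate_scope denominator for criterion 2: `"within_group"`
#'   (adult males of the group; the default, matching the randomization pool)
#'   or `"population"` (all adult males in any group at the attempt date)
#' @param confidence parentage acceptance threshold (default 0.8)
#' @return list with `dyads` (data.frame `attempt_id, female_id, male_id, r`)
#'   and `report` (a `filter_report`)
#' @export
breeding_pair_filter <- function(dataset, a, natal_only = FALSE,
                                 candidate_scope = c("within_group", "population"),
                                 confidence = 0.8) {
  candidate_scope <- match.arg(candidate_scope)
  p <- dataset$parentage
  ok <- !is.na(p$dam_id) & !is.na(p$sire_id) &
    !is.na(p$dam_confidence) & p$dam_confidence >= confidence &
    !is.na(p$sire_confidence) & p$sire_confidence >= confidence &
    p$attempt_id %in% dataset$attempts$attempt_id
  d <- unique(p[ok, c("attempt_id", "dam_id", "sire_id")])
  names(d) <- c("attempt_id", "female_id", "male_id")
  rownames(d) <- NULL
  if (natal_only)
    d <- d[d$attempt_id %in% natal_attempts(dataset, c("F", "M")), , drop = FALSE]

  assigned <- assigned_parents_ids(dataset, confidence)
  c1 <- d$female_id %in% assigned
  c2 <- vapply(unique(d$attempt_id), function(at) {
    cand <- if (candidate_scope == "within_group")
      candidate_adults(dataset, at, "M")
    else {
      m <- dataset$membership
      sort(unique(m$individual_id[m$sex %in% "M" & !is.na(m$age_days) &
                                    m$age_days > 365 &
                                    m$attempt_id %in% same_date_attempts(dataset, at)]))
    }
    length(cand) > 0 && mean(cand %in% assigned) >= 0.8
  }, TRUE)[match(d$attempt_id, unique(d$attempt_id))]
  c3 <- in_roster(dataset, d$attempt_id, d$male_id)
  crit <- data.frame(mother_parents_assigned = c1,
                     candidate_fathers_80pct = c2,
                     sire_within_group = c3)
  keep <- rowSums(!as.matrix(crit), na.rm = TRUE) == 0 & stats::complete.cases(crit)
  dy <- d[keep, , drop = FALSE]
  dy$r <- if (nrow(dy)) relatedness(a, dy$female_id, dy$male_id) else numeric(0)
  name <- if (natal_only) "breeding_pairs_natal" else "breeding_pairs"
  list(dyads = dy, report = make_filter_report(name, crit, dy[, 1:3]))
}

# attempts in any group whose oestrus date falls within 30 d of this one's
# (population-wide candidate-father scope)
same_date_attempts <- function(dataset, attempt_id) {
  at <- dataset$attempts
  d0 <- at$oestrus_start_date[at$attempt_id == attempt_id]
  at$attempt_id[!is.na(at$oestrus_start_date) &
                  abs(as.numeric(at$oestrus_start_date - d0)) <= 30]
}

#' Guard-female dyad inclusion filter
#'
#' Applies to the observed mate-guarding records: (1) the mate-guard has both
#' parents confidently assigned; (2) at least 80\% of candidate females (the
#' females observed guarded in the same oestrus event, i.e. the randomization
#' pool) have confidently assigned parents. With `natal_only = TRUE` the input
#' is first limited to attempts where every adult female is natal.
#'
#' @inheritParams breeding_pair_filter
#' @return list with `dyads` (data.frame `attempt_id, male_id, female_id, r,
#'   n_days_guarding`) and `report`
#' @export
guard_pair_filter <- function(dataset, a, natal_only = FALSE, confidence = 0.8) {
  g <- dataset$guards
  d <- data.frame(attempt_id = g$attempt_id, male_id = g$guard_id,
                  female_id = g$female_id,
                  n_days_guarding = g$n_days_guarding,
                  stringsAsFactors = FALSE)
  if (natal_only)
    d <- d[d$attempt_id %in% natal_attempts(dataset, "F"), , drop = FALSE]
  assigned <- assigned_parents_ids(dataset, confidence)
  c1 <- d$male_id %in% assigned
  pool_ok <- vapply(unique(d$attempt_id), function(at) {
    fem <- unique(d$female_id[d$attempt_id == at])
    length(fem) > 0 && mean(fem %in% assigned) >= 0.8
  }, TRUE)
  c2 <- pool_ok[match(d$attempt_id, unique(d$attempt_id))]
  crit <- data.frame(guard_parents_assigned = c1,
                     candidate_females_80pct = c2)
  keep <- c1 & c2
  dy <- d[keep, , drop = FALSE]
  rownames(dy) <- NULL
  dy$r <- if (nrow(dy)) relatedness(a, dy$female_id, dy$male_id) else numeric(0)
  name <- if (natal_only) "guard_pairs_natal" else "guard_pairs"
  list(dyads = dy, report = make_filter_report(name, crit, dy[, 1:3]))
}

#' Classify mate-guards as successful or unsuccessful
#'
#' A guard-female pair is classifiable when the female was confidently
#' assigned at least one offspring born 40-80 days after the observed oestrus
#' start; the guard is `successful` when at least one such offspring has the
#' guard as its assigned sire. Pairs whose female has no assigned offspring in
#' the window are excluded (not classified).
#'
#' @param dataset a `study_dataset`
#' @param confidence parentage acceptance threshold
#' @param window days after oestrus start within which a birth is attributed
#'   to the oestrus (default `c(40, 80)`)
#' @return data.frame `attempt_id, guard_id, female_id, n_days_guarding,
#'   success` (logical), one row per classifiable guard observation
#' @export
classify_guard_success <- function(dataset, confidence = 0.8,
                                   window = c(40, 80)) {
  g <- dataset$guards
  at <- dataset$attempts
  p <- dataset$parentage
  p <- p[!is.na(p$dam_id) & !is.na(p$sire_id) &
           !is.na(p$dam_confidence) & p$dam_confidence >= confidence &
           !is.na(p$sire_confidence) & p$sire_confidence >= confidence, ,
         drop = FALSE]
  ped <- dataset$pedigree
  off_birth <- ped$birth_date[match(p$offspring_id, ped$id)]
  na_b <- is.na(off_birth)
  off_birth[na_b] <- at$birth_date[match(p$attempt_id[na_b], at$attempt_id)]
  oest <- at$oestrus_start_date[match(g$attempt_id, at$attempt_id)]

  out <- g[, c("attempt_id", "guard_id", "female_id", "n_days_guarding")]
  out$success <- NA
  for (i in seq_len(nrow(out))) {
    if (is.na(oest[i])) next
    lag <- as.numeric(off_birth - oest[i])
    sel <- p$dam_id == out$female_id[i] & !is.na(lag) &
      lag >= window[1] & lag <= window[2]
    if (!any(sel)) next
    out$success[i] <- out$guard_id[i] %in% p$sire_id[sel]
  }
  out[!is.na(out$success), , drop = FALSE]
}

#' Identify extra-pair paternity (EPP) events paired with their mate-guard
#'
#' For every unsuccessful guard-female pair (see [classify_guard_success()])
#' with exactly one distinct non-guard sire among the female's window
#' offspring, returns the female's relatedness to her guard and to the EPP
#' male, and whether the EPP male was in the female's group at the attempt
#' (`within_group`) or not (`extra_group`). Criteria: guard, female and EPP
#' male all have confidently assigned parents; pairs with two or more distinct
#' EPP identities are excluded (no unique paired comparison).
#'
#' @inheritParams breeding_pair_filter
#' @param window birth-attribution window, as in [classify_guard_success()]
#' @return list with `pairs` (data.frame `attempt_id, female_id, guard_id,
#'   epp_id, guard_r, epp_r, epp_scope`) and `report`
#' @export
identify_epp <- function(dataset, a, natal_only = FALSE, confidence = 0.8,
                         window = c(40, 80)) {
  cls <- classify_guard_success(dataset, confidence, window)
  if (natal_only)
    cls <- cls[cls$attempt_id %in% natal_attempts(dataset, "M"), , drop = FALSE]
  un <- cls[!cls$success, , drop = FALSE]

  at <- dataset$attempts
  p <- dataset$parentage
  p <- p[!is.na(p$dam_id) & !is.na(p$sire_id) &
           !is.na(p$dam_confidence) & p$dam_confidence >= confidence &
           !is.na(p$sire_confidence) & p$sire_confidence >= confidence, ,
         drop = FALSE]
  ped <- dataset$pedigree
  off_birth <- ped$birth_date[match(p$offspring_id, ped$id)]
  na_b <- is.na(off_birth)
  off_birth[na_b] <- at$birth_date[match(p$attempt_id[na_b], at$attempt_id)]
  oest <- at$oestrus_start_date[match(un$attempt_id, at$attempt_id)]

  epp_id <- rep(NA_character_, nrow(un))
  n_epp <- integer(nrow(un))
  for (i in seq_len(nrow(un))) {
    lag <- as.numeric(off_birth - oest[i])
    sel <- p$dam_id == un$female_id[i] & !is.na(lag) &
      lag >= window[1] & lag <= window[2]
    sires <- setdiff(unique(p$sire_id[sel]), un$guard_id[i])
    n_epp[i] <- length(sires)
    if (length(sires) == 1L) epp_id[i] <- sires
  }
  assigned <- assigned_parents_ids(dataset, confidence)
  crit <- data.frame(single_epp_identity = n_epp == 1L,
                     guard_parents_assigned = un$guard_id %in% assigned,
                     female_parents_assigned = un$female_id %in% assigned,
                     epp_parents_assigned = !is.na(epp_id) & epp_id %in% assigned)
  keep <- rowSums(!as.matrix(crit)) == 0L
  pr <- data.frame(attempt_id = un$attempt_id[keep],
                   female_id = un$female_id[keep],
                   guard_id = un$guard_id[keep],
                   epp_id = epp_id[keep], stringsAsFactors = FALSE)
  rownames(pr) <- NULL
  if (nrow(pr)) {
    pr$guard_r <- relatedness(a, pr$female_id, pr$guard_id)
    pr$epp_r <- relatedness(a, pr$female_id, pr$epp_id)
    pr$epp_scope <- ifelse(in_roster(dataset, pr$attempt_id, pr$epp_id),
                           "within_group", "extra_group")
  } else {
    pr$guard_r <- pr$epp_r <- numeric(0)
    pr$epp_scope <- character(0)
  }
  name <- if (natal_only) "epp_pairs_natal" else "epp_pairs"
  list(pairs = pr, report = make_filter_report(name, crit, pr[, 1:4]))
}

#' Serialize a filter report to JSON
#'
#' @param report a `filter_report`
#' @param path output path
#' @return the path, invisibly
#' @export
write_filter_report <- function(report, path) {
  x <- report[c("analysis_name", "n_input", "per_criterion_pass_counts",
                "n_retained", "dropped_by")]
  x$per_criterion_pass_counts <- as.list(x$per_criterion_pass_counts)
  x$dropped_by <- as.list(x$dropped_by)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
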