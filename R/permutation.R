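#' @name permutation_tests
#' @title Constrained randomization tests for non-random pairing
#'
#' @description The null hypothesis of random within-group pairing is
#' represented by constrained reshuffles of the observed dyads: breeding
#' dyads reassign each mother to random adult males of her group (as many
#' distinct males as she had distinct sires); guard dyads reshuffle guarded
#' females over guard slots within each oestrus event, preserving every
#' male's and every female's number of guarding links. The observed mean
#' pairwise relatedness is compared to the permutation distribution with a
#' one-tailed Monte Carlo P (direction: lower relatedness than expected),
#' using the add-one convention p = (1 + #\{null <= observed\}) / (n_perms + 1).
NULL

# --- breeding dyads ---------------------------------------------------------

# Decompose retained dyads into per-(attempt, female) sampling units.
# Units whose candidate pool is smaller than the female's distinct-sire count
# are excluded from both the observed and the null sets (flagged).
breeding_perm_structure <- function(dyads, dataset, a) {
  key <- paste(dyads$attempt_id, dyads$female_id, sep = "\r")
  units <- list()
  excluded <- logical(nrow(dyads))
  for (g in split(seq_len(nrow(dyads)), key)) {
    at <- dyads$attempt_id[g[1]]
    fem <- dyads$female_id[g[1]]
    cand <- candidate_adults(dataset, at, "M")
    k <- length(unique(dyads$male_id[g]))
    if (length(cand) < k) {
      excluded[g] <- TRUE
      next
    }
    units[[length(units) + 1L]] <- list(
      rows = g, k = k, r_cand = unname(a[fem, cand]))
  }
  list(units = units, excluded = excluded)
}

#' Draw one constrained randomization of breeding dyads
#'
#' Each mother (per attempt) is reassigned to as many distinct random adult
#' males from her group as she had distinct assigned sires; males may be
#' reused across females. Dyads whose candidate pool is smaller than the
#' required number of males are dropped (with a warning).
#'
#' @param dyads retained dyads from [breeding_pair_filter()]
#' @param dataset a `study_dataset`
#' @param a relatedness matrix
#' @return data.frame like `dyads` with permuted `male_id` and `r`
#' @export
randomize_breeding_dyads <- function(dyads, dataset, a) {
  st <- breeding_perm_structure(dyads, dataset, a)
  if (any(st$excluded))
    warning(sum(st$excluded), " dyad(s) excluded: candidate pool too small")
  keep <- which(!st$excluded)
  out <- dyads[keep, , drop = FALSE]
  for (u in st$units) {
    rows <- u$rows
    cand <- candidate_adults(dataset, dyads$attempt_id[rows[1]], "M")
    pick <- cand[sample.int(length(cand), u$k)]
    out$male_id[match(rows, keep)] <- pick
  }
  out$r <- relatedness(a, out$female_id, out$male_id)
  out
}

# --- guard dyads ------------------------------------------------------------

# One degree-preserving reshuffle of female endpoints over guard slots within
# an event, with no duplicate (male, female) edge. Uniform over valid
# configurations: rejection sampling of slot permutations, falling back to
# exhaustive enumeration for small events; degenerate events keep their
# observed edges.
shuffle_event <- function(males, females, max_retry = 10000L) {
  n <- length(females)
  if (n <= 1L) return(females)
  for (t in seq_len(max_retry)) {
    perm <- females[sample.int(n, n)]
    if (!anyDuplicated(paste(males, perm, sep = "\r"))) return(perm)
  }
  if (n <= 8L) {
    perms <- all_permutations(n)
    valid <- perms[vapply(seq_len(nrow(perms)), function(i) {
      !anyDuplicated(paste(males, females[perms[i, ]], sep = "\r"))
    }, TRUE), , drop = FALSE]
    if (nrow(valid) == 0L) return(females)  # degenerate: keep observed
    return(females[valid[sample.int(nrow(valid), 1L), ]])
  }
  females  # degenerate large event: keep observed (logged by caller)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                   sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  out
}

#' Draw one constrained randomization of guard-female dyads
#'
#' Within each oestrus event the multiset of guarded-female endpoints is
#' permuted over guard slots, preserving each male's and each female's number
#' of guarding links, with no duplicate (male, female) edge.
#'
#' @param dyads retained dyads from [guard_pair_filter()]
#' @param dataset a `study_dataset` (used only for grouping by attempt)
#' @param a relatedness matrix
#' @return data.frame like `dyads` with permuted `female_id` and `r`
#' @export
randomize_guard_dyads <- function(dyads, dataset, a) {
  out <- dyads
  for (g in split(seq_len(nrow(out)), out$attempt_id)) {
    out$female_id[g] <- shuffle_event(out$male_id[g], out$female_id[g])
  }
  out$r <- relatedness(a, out$female_id, out$male_id)
  out
}

# --- the test ---------------------------------------------------------------

#' One-tailed Monte Carlo permutation test of mean dyad relatedness
#'
#' Compares the observed mean pairwise relatedness of the retained dyads with
#' its distribution under `n_perms` constrained randomizations. The test is
#' one-tailed for *lower* relatedness than expected under random pairing;
#' ties (a null mean exactly equal to the observed mean) count as at least as
#' extreme, and the Monte Carlo P uses the add-one convention, so p is never 0.
#'
#' @param dyads retained dyads (`breeding_pair_filter()` or
#'   [guard_pair_filter()] output `$dyads`)
#' @param dataset a `study_dataset`
#' @param a relatedness matrix
#' @param type `"breeding"` (reassign males per female) or `"guard"`
#'   (degree-preserving reshuffle within events)
#' @param n_perms number of permutations (>= 1; 10 000 by default)
#' @param seed integer seed (reproducible)
#' @param analysis_name label carried into the result
#' @return a `permutation_result`: list with `analysis_name`,
#'   `observed_mean`, `null_means`, `p_one_tailed`, `n_perms`, `seed`,
#'   `n_dyads`, `n_excluded`
#' @export
permutation_test <- function(dyads, dataset, a,
                             type = c("breeding", "guard"),
                             n_perms = 10000L, seed = 1L,
                             analysis_name = type) {
  type <- match.arg(type)
  if (is.null(dyads) || nrow(dyads) == 0L) stop("empty dyad set")
  stopifnot(n_perms >= 1)
  analysis_name <- analysis_name[1]

  if (type == "breeding") {
    st <- breeding_perm_structure(dyads, dataset, a)
    n_excluded <- sum(st$excluded)
    obs <- dyads[!st$excluded, , drop = FALSE]
    if (nrow(obs) == 0L) stop("empty dyad set after pool-size exclusions")
    n_dyads <- nrow(obs)
    observed_mean <- mean(relatedness(a, obs$female_id, obs$male_id))
    totals <- local_seed(seed, {
      tot <- numeric(n_perms)
      for (u in st$units) {
        m <- length(u$r_cand)
        if (u$k == 1L) {
          tot <- tot + u$r_cand[sample.int(m, n_perms, replace = TRUE)]
        } else if (u$k == 2L) {
          # distinct pair, uniform: partial Fisher-Yates, vectorized
          i1 <- sample.int(m, n_perms, replace = TRUE)
          i2 <- sample.int(m - 1L, n_perms, replace = TRUE)
          i2 <- i2 + (i2 >= i1)
          tot <- tot + u$r_cand[i1] + u$r_cand[i2]
        } else {
          tot <- tot + vapply(seq_len(n_perms), function(i)
            sum(u$r_cand[sample.int(m, u$k)]), 0)
        }
      }
      tot
    })
    null_means <- totals / n_dyads
  } else {
    n_excluded <- 0L
    n_dyads <- nrow(dyads)
    observed_mean <- mean(relatedness(a, dyads$female_id, dyads$male_id))
    events <- split(seq_len(nrow(dyads)), dyads$attempt_id)
    null_means <- local_seed(seed, {
      vapply(seq_len(n_perms), function(i) {
        tot <- 0
        for (g in events) {
          fem <- shuffle_event(dyads$male_id[g], dyads$female_id[g])
          tot <- tot + sum(a[cbind(fem, dyads$male_id[g])])
        }
        tot / n_dyads
      }, 0)
    })
  }

  structure(list(analysis_name = analysis_name,
                 observed_mean = observed_mean,
                 null_means = null_means,
                 p_one_tailed = (1 + sum(null_means <= observed_mean)) /
                   (n_perms + 1),
                 n_perms = as.integer(n_perms), seed = as.integer(seed),
                 n_dyads = n_dyads, n_excluded = n_excluded),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("permutation_result [%s]: observed mean r = %.4f, ",
                     "null mean = %.4f, one-tailed P = %.4g ",
                     "(%d dyads, %d permutations)\n"),
              x$analysis_name, x$observed_mean, mean(x$null_means),
              x$p_one_tailed, x$n_dyads, x$n_perms))
  invisible(x)
}

#' Write a permutation result to JSON (and optionally the null means to CSV)
#'
#' @param result a `permutation_result`
#' @param path JSON output path
#' @param null_csv optional CSV path for the null means
#' @return `path`, invisibly
#' @export
write_permutation_result <- function(result, path, null_csv = NULL) {
  x <- result[c("analysis_name", "observed_mean", "p_one_tailed", "n_perms",
                "seed", "n_dyads", "n_excluded")]
  x$null_mean <- mean(result$null_means)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(null_csv))
    utils::write.csv(data.frame(null_mean = result$null_means), null_csv,
                     row.names = FALSE)
  invisible(path)
}
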