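#' Validate a pedigree and order it parents-first
#'
#' Checks a table of pedigree records (one row per individual, with optional
#' dam/sire links) and returns a `pedigree` object whose rows are in a
#' topological order: every known parent precedes all of its offspring.
#' Parent identifiers that do not occur as records ("dangling" references)
#' are promoted to founder records with a warning, so that shared unknown
#' parents still induce sibship.
#'
#' @param records data.frame with columns `id`, `dam`, `sire` and optionally
#'   `sex` (`"F"`, `"M"` or `NA`), `birth_date` (`Date` or ISO-8601 string),
#'   `natal_group`. Missing parents are `NA` or `""`.
#' @return A `pedigree`: the record data.frame in topological order with
#'   integer attribute columns `dam_idx`, `sire_idx` (row index of each known
#'   parent, `NA` if unknown).
#' @details Hard errors: duplicated `id`; an ancestry cycle (the error names a
#'   cycle member). Warnings: dangling parent references; a known dam recorded
#'   as male (or sire as female); a parent whose known birth date does not
#'   precede its offspring's.
#' @examples
#' ped <- validate_pedigree(data.frame(
#'   id = c("A", "B", "C"), dam = c(NA, NA, "A"), sire = c(NA, NA, "B"),
#'   sex = c("F", "M", "F")))
#' ped$id
#' @export
validate_pedigree <- function(records) {
  stopifnot(is.data.frame(records), all(c("id", "dam", "sire") %in% names(records)))
  rec <- as.data.frame(records, stringsAsFactors = FALSE)
  rec$id <- as.character(rec$id)
  for (col in c("dam", "sire")) {
    v <- as.character(rec[[col]])
    v[!is.na(v) & v == ""] <- NA_character_
    rec[[col]] <- v
  }
  if (anyDuplicated(rec$id))
    stop("duplicate individual id(s): ",
         paste(unique(rec$id[duplicated(rec$id)]), collapse = ", "))
  for (col in c("sex", "birth_date", "natal_group"))
    if (is.null(rec[[col]])) rec[[col]] <- NA
  rec$sex <- normalize_sex(rec$sex)
  rec$birth_date <- as.Date(rec$birth_date)

  # promote dangling parent references to founder records
  dangling_dam <- setdiff(stats::na.omit(rec$dam), rec$id)
  dangling_sire <- setdiff(stats::na.omit(rec$sire), rec$id)
  dangling <- union(dangling_dam, dangling_sire)
  if (length(dangling)) {
    warning("dangling parent reference(s) treated as founders: ",
            paste(dangling, collapse = ", "))
    add <- data.frame(id = dangling, dam = NA_character_, sire = NA_character_,
                      sex = ifelse(dangling %in% dangling_dam,
                                   ifelse(dangling %in% dangling_sire, NA, "F"), "M"),
                      birth_date = as.Date(NA), natal_group = NA,
                      stringsAsFactors = FALSE)
    rec <- rbind(rec[, c("id", "dam", "sire", "sex", "birth_date", "natal_group")],
                 add)
  } else {
    rec <- rec[, c("id", "dam", "sire", "sex", "birth_date", "natal_group")]
  }

  n <- nrow(rec)
  idx <- seq_len(n)
  names(idx) <- rec$id
  dam_i <- unname(idx[rec$dam])
  sire_i <- unname(idx[rec$sire])

  # sex consistency of parent roles
  bad_dam <- which(!is.na(dam_i) & rec$sex[dam_i] %in% "M")
  bad_sire <- which(!is.na(sire_i) & rec$sex[sire_i] %in% "F")
  if (length(bad_dam) || length(bad_sire))
    warning("parent sex inconsistent with role for offspring: ",
            paste(rec$id[union(bad_dam, bad_sire)], collapse = ", "))

  ord <- topo_order(dam_i, sire_i, rec$id)
  rec <- rec[ord, , drop = FALSE]
  rownames(rec) <- NULL
  idx2 <- seq_len(n)
  names(idx2) <- rec$id
  rec$dam_idx <- unname(idx2[rec$dam])
  rec$sire_idx <- unname(idx2[rec$sire])

  # birth-date ordering (parents born before offspring) where both known
  for (side in c("dam_idx", "sire_idx")) {
    p <- rec[[side]]
    ok <- !is.na(p) & !is.na(rec$birth_date) & !is.na(rec$birth_date[ifelse(is.na(p), 1L, p)])
    bad <- which(ok & rec$birth_date[ifelse(is.na(p), 1L, p)] >= rec$birth_date)
    if (length(bad))
      warning("parent birth date not before offspring for: ",
              paste(rec$id[bad], collapse = ", "))
  }

  class(rec) <- c("pedigree", "data.frame")
  rec
}

normalize_sex <- function(x) {
  x <- toupper(substr(as.character(x), 1, 1))
  out <- ifelse(x %in% c("F", "M"), x, NA_character_)
  out
}

# Kahn's algorithm; on failure names one member of a remaining cycle.
topo_order <- function(dam_i, sire_i, ids) {
  n <- length(ids)
  self <- which(!is.na(dam_i) & dam_i == seq_len(n) |
                  !is.na(sire_i) & sire_i == seq_len(n))
  if (length(self))
    stop("ancestry cycle involving: ", ids[self[1]])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(dam_i[i], sire_i[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    stop("ancestry cycle involving: ", ids[setdiff(seq_len(n), out)[1]])
  }
  out
}

is_pedigree <- function(x) inherits(x, "pedigree")

#' Kinship (coancestry) matrix of a pedigree
#'
#' Computes the full matrix of kinship coefficients f(i, j) — the probability
#' that one allele drawn at random from i and one from j are identical by
#' descent — by the standard tabular recursion over the topological order:
#' f(i,i) = (1 + f(dam_i, sire_i)) / 2 and, for j ordered before i,
#' f(i,j) = (f(dam_i, j) + f(sire_i, j)) / 2, with unknown parents contributing
#' kinship 0. Founders are assumed non-inbred and mutually unrelated.
#'
#' @param ped a `pedigree` from [validate_pedigree()]
#' @return symmetric numeric matrix with the individual ids as dimnames
#' @export
kinship_matrix <- function(ped) {
  if (!is_pedigree(ped)) stop("input must be a validated pedigree")
  n <- nrow(ped)
  f <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  dam_i <- ped$dam_idx
  sire_i <- ped$sire_idx
  for (i in seq_len(n)) {
    d <- dam_i[i]
    s <- sire_i[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      fd <- if (is.na(d)) 0 else f[d, j]
      fs <- if (is.na(s)) 0 else f[s, j]
      row <- (fd + fs) / 2
      f[i, j] <- row
      f[j, i] <- row
    }
    fds <- if (is.na(d) || is.na(s)) 0 else f[d, s]
    f[i, i] <- (1 + fds) / 2
  }
  f
}

#' Additive (numerator) relatedness matrix
#'
#' Returns A = 2 f, the numerator relationship matrix: a_ij = 2 f(i, j), with
#' diagonal a_ii = 1 + F_i. Outbred parent-offspring pairs and full sibs have
#' a = 0.5; founders are mutually 0.
#'
#' @param ped a `pedigree`, or a kinship matrix from [kinship_matrix()]
#' @return symmetric numeric matrix of class `relatedness_matrix`
#' @export
relatedness_matrix <- function(ped) {
  f <- if (is_pedigree(ped)) kinship_matrix(ped) else ped
  a <- 2 * f
  class(a) <- c("relatedness_matrix", class(a))
  a
}

#' Pairwise relatedness lookup
#'
#' @param a relatedness matrix from [relatedness_matrix()]
#' @param i,j individual ids
#' @return a_ij in \[0, 2\]
#' @export
relatedness <- function(a, i, j) {
  miss <- setdiff(unique(c(i, j)), rownames(a))
  if (length(miss))
    stop("id(s) not in relatedness matrix: ", paste(miss, collapse = ", "))
  a[cbind(i, j)]
}

#' Inbreeding coefficients from a pedigree
#'
#' F_i is the kinship of i's parents: the probability that i's two alleles at
#' a locus are identical by descent. Individuals with any unknown parent have
#' F = 0 under the founder convention (each missing parent is a unique,
#' unrelated founder).
#'
#' @param ped a `pedigree`
#' @param kinship optional precomputed kinship matrix (recomputed if `NULL`)
#' @return data.frame with columns `individual_id`, `F`, `parents_known`
#' @export
inbreeding <- function(ped, kinship = NULL) {
  if (!is_pedigree(ped)) stop("input must be a validated pedigree")
  f <- if (is.null(kinship)) kinship_matrix(ped) else kinship
  F_i <- 2 * diag(f) - 1
  data.frame(individual_id = ped$id,
             F = unname(F_i),
             parents_known = !is.na(ped$dam_idx) & !is.na(ped$sire_idx),
             stringsAsFactors = FALSE)
}

#' Monte Carlo gene-dropping estimates of F and relatedness
#'
#' Independent validation oracle for the kinship recursion: assigns two unique
#' alleles to every founder (and to each missing parent side), transmits one
#' allele per parent uniformly at random per replicate, and estimates F as the
#' fraction of replicates in which an individual's two alleles are identical
#' by descent, and relatedness as twice the observed coancestry (the
#' probability that two alleles drawn one from each individual match).
#'
#' @param ped a `pedigree`
#' @param n_replicates number of Monte Carlo replicates (>= 1)
#' @param seed integer seed; results are reproducible for a fixed seed
#' @return list with `F` (named numeric), `r` (matrix; diagonal 1 + F_hat),
#'   `kinship` (matrix of coancestry estimates) and `n_replicates`
#' @export
gene_drop <- function(ped, n_replicates = 10000L, seed = 1L) {
  if (!is_pedigree(ped)) stop("input must be a validated pedigree")
  stopifnot(n_replicates >= 1)
  dam0 <- ifelse(is.na(ped$dam_idx), -1L, ped$dam_idx - 1L)
  sire0 <- ifelse(is.na(ped$sire_idx), -1L, ped$sire_idx - 1L)
  res <- local_seed(seed, .gene_drop_cpp(dam0, sire0, as.integer(n_replicates)))
  f_hat <- res$match_sum / (4 * n_replicates)
  F_hat <- res$ibd_count / n_replicates
  r_hat <- 2 * f_hat
  diag(r_hat) <- 1 + F_hat
  dimnames(r_hat) <- list(ped$id, ped$id)
  dimnames(f_hat) <- list(ped$id, ped$id)
  list(F = stats::setNames(F_hat, ped$id), r = r_hat, kinship = f_hat,
       n_replicates = n_replicates)
}

#' Read a pedigree CSV
#'
#' Expects columns `id,dam,sire,sex,birth_date,natal_group` (extra columns are
#' ignored; empty fields are unknown). Comma- or tab-delimited, auto-sniffed;
#' tolerates a UTF-8 byte-order mark.
#'
#' @param path file path
#' @return a validated `pedigree`
#' @export
read_pedigree_csv <- function(path) {
  tab <- read_delim_auto(path)
  need <- c("id", "dam", "sire")
  if (!all(need %in% names(tab)))
    stop("pedigree file must have columns: ", paste(need, collapse = ", "))
  validate_pedigree(tab)
}

#' Write relatedness in long format and the inbreeding table
#'
#' `write_relatedness_long()` emits `id1,id2,r` rows for the upper triangle
#' (including the diagonal); `write_inbreeding()` emits `id,F`.
#'
#' @param a relatedness matrix
#' @param ped a `pedigree`
#' @param path output CSV path
#' @return the path, invisibly
#' @export
write_relatedness_long <- function(a, path) {
  ut <- upper.tri(a, diag = TRUE)
  idx <- which(ut, arr.ind = TRUE)
  out <- data.frame(id1 = rownames(a)[idx[, 1]], id2 = colnames(a)[idx[, 2]],
                    r = a[ut])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_relatedness_long
#' @export
write_inbreeding <- function(ped, path) {
  tab <- inbreeding(ped)
  utils::write.csv(data.frame(id = tab$individual_id, F = tab$F), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
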