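#' @name regression_models
#' @title Inbreeding-depression and guard-success mixed models
#'
#' @description Model frames pair each response with the covariates and
#' grouping factors of the corresponding analysis; [fit_and_simplify()] then
#' applies the backward-elimination procedure: terms are dropped one at a time
#' (least significant first, likelihood-ratio chi-square on ML fits) until all
#' remaining terms are significant at P < 0.05, and every dropped term is then
#' put back into the minimal model individually to obtain its effect size and
#' level of non-significance.
NULL

#' Build the yearling body-mass model frame
#'
#' Response: body mass (g) of yearlings, restricted to records taken at
#' 350-370 days of age. Fixed effects: inbreeding coefficient F, age in days,
#' maternal age, group size (adults at birth), number of pups born in the
#' attempt, and mean daily rainfall in the 30 days before birth. Grouping
#' factors: social group, breeding attempt (the communal litter), maternal
#' identity, paternal identity and individual identity. Individuals without
#' both parents assigned have no defined F and are excluded, as are rows with
#' any missing covariate (counts logged).
#'
#' @param dataset a `study_dataset`
#' @param inbreeding_tab data.frame from [inbreeding()]
#' @param maternal_age_unit `"months"` (default) or `"years"`
#' @param age_window inclusive age range in days (default `c(350, 370)`)
#' @return data.frame with a `model_spec` attribute consumed by
#'   [fit_and_simplify()]
#' @export
build_mass_frame <- function(dataset, inbreeding_tab,
                             maternal_age_unit = c("months", "years"),
                             age_window = c(350, 370)) {
  maternal_age_unit <- match.arg(maternal_age_unit)
  o <- dataset$outcomes
  o <- o[!is.na(o$body_mass_g) & !is.na(o$age_days) &
           o$age_days >= age_window[1] & o$age_days <= age_window[2], ,
         drop = FALSE]
  fr <- cbind(o[, c("individual_id", "age_days")],
              mass = o$body_mass_g,
              individual_covariates(dataset, inbreeding_tab, o$individual_id,
                                    maternal_age_unit))
  n0 <- nrow(fr)
  fr <- fr[stats::complete.cases(fr), , drop = FALSE]
  if (nrow(fr) < n0)
    message("build_mass_frame: dropped ", n0 - nrow(fr),
            " row(s) with missing F or covariates")
  for (col in c("group_id", "attempt_id", "dam_id", "sire_id", "individual_id"))
    fr[[col]] <- factor(fr[[col]])
  attr(fr, "model_spec") <- list(
    response = "mass", family = "gaussian",
    fixed = c("F", "age_days", "maternal_age", "group_size", "n_pups",
              "rainfall_30d"),
    random = c("group_id", "attempt_id", "dam_id", "sire_id", "individual_id"))
  fr
}

#' Build the survival-to-one-year model frame
#'
#' Binomial response: whether the individual survived to 1 year. Same fixed
#' effects as the body-mass model except age at measurement; grouping
#' factors: social group, breeding attempt, maternal and paternal identity.
#'
#' @inheritParams build_mass_frame
#' @return data.frame with a `model_spec` attribute
#' @export
build_survival_frame <- function(dataset, inbreeding_tab,
                                 maternal_age_unit = c("months", "years")) {
  maternal_age_unit <- match.arg(maternal_age_unit)
  o <- dataset$outcomes
  o <- unique(o[!is.na(o$survived_to_1yr), c("individual_id", "survived_to_1yr")])
  fr <- cbind(o[, "individual_id", drop = FALSE],
              survived = as.integer(o$survived_to_1yr),
              individual_covariates(dataset, inbreeding_tab, o$individual_id,
                                    maternal_age_unit))
  n0 <- nrow(fr)
  fr <- fr[stats::complete.cases(fr), , drop = FALSE]
  if (nrow(fr) < n0)
    message("build_survival_frame: dropped ", n0 - nrow(fr),
            " row(s) with missing F or covariates")
  for (col in c("group_id", "attempt_id", "dam_id", "sire_id"))
    fr[[col]] <- factor(fr[[col]])
  attr(fr, "model_spec") <- list(
    response = "survived", family = "binomial",
    fixed = c("F", "maternal_age", "group_size", "n_pups", "rainfall_30d"),
    random = c("group_id", "attempt_id", "dam_id", "sire_id"))
  fr
}

# per-individual covariates shared by the mass and survival frames
individual_covariates <- function(dataset, inbreeding_tab, ids,
                                  maternal_age_unit) {
  p <- dataset$parentage
  pidx <- match(ids, p$offspring_id)
  at <- dataset$attempts
  aidx <- match(p$attempt_id[pidx], at$attempt_id)
  ped <- dataset$pedigree
  birth <- ped$birth_date[match(ids, ped$id)]
  birth[is.na(birth)] <- at$birth_date[aidx][is.na(birth)]
  dam <- p$dam_id[pidx]
  dam_birth <- ped$birth_date[match(dam, ped$id)]
  mat_age <- as.numeric(birth - dam_birth) /
    if (maternal_age_unit == "months") 30.44 else 365.25
  Fi <- inbreeding_tab$F[match(ids, inbreeding_tab$individual_id)]
  Fi[!inbreeding_tab$parents_known[match(ids, inbreeding_tab$individual_id)]] <- NA
  data.frame(F = Fi,
             maternal_age = mat_age,
             group_size = at$group_size_adults[aidx],
             n_pups = at$n_pups_born[aidx],
             rainfall_30d = at$rainfall_30d[aidx],
             group_id = at$group_id[aidx],
             attempt_id = p$attempt_id[pidx],
             dam_id = dam,
             sire_id = p$sire_id[pidx],
             stringsAsFactors = FALSE)
}

#' Build the mate-guard success model frame
#'
#' Binomial response: whether a mate-guard gained paternity with his guarded
#' female (see [classify_guard_success()]). Rows are limited to pairs where
#' both guard and female have confidently assigned parents and are of known
#' age rank / age. Fixed effects: guard-female relatedness, male age rank,
#' female age (months), group sex ratio (proportion of adults that are male)
#' and the number of guarding days. Grouping factors: social group, breeding
#' attempt, guard identity and female identity.
#'
#' @param dataset a `study_dataset`
#' @param a relatedness matrix
#' @param natal_only restrict to attempts where all adult males are natal
#' @param confidence parentage acceptance threshold
#' @return data.frame with a `model_spec` attribute
#' @export
build_guard_success_frame <- function(dataset, a, natal_only = FALSE,
                                      confidence = 0.8) {
  cls <- classify_guard_success(dataset, confidence)
  if (natal_only)
    cls <- cls[cls$attempt_id %in% natal_attempts(dataset, "M"), , drop = FALSE]
  assigned <- assigned_parents_ids(dataset, confidence)
  m <- dataset$membership
  mk <- paste(m$attempt_id, m$individual_id)
  g_idx <- match(paste(cls$attempt_id, cls$guard_id), mk)
  f_idx <- match(paste(cls$attempt_id, cls$female_id), mk)
  at <- dataset$attempts
  ad <- m[!is.na(m$age_days) & m$age_days > 365, , drop = FALSE]
  sexr <- tapply(ad$sex == "M", ad$attempt_id, mean)

  fr <- data.frame(
    success = as.integer(cls$success),
    guard_female_r = relatedness(a, cls$female_id, cls$guard_id),
    male_age_rank = m$age_rank[g_idx],
    female_age = m$age_days[f_idx] / 30.44,
    sex_ratio = as.numeric(sexr[as.character(cls$attempt_id)]),
    n_days_guarding = cls$n_days_guarding,
    group_id = at$group_id[match(cls$attempt_id, at$attempt_id)],
    attempt_id = cls$attempt_id,
    guard_id = cls$guard_id,
    female_id = cls$female_id,
    stringsAsFactors = FALSE)
  keep <- cls$guard_id %in% assigned & cls$female_id %in% assigned &
    !is.na(fr$male_age_rank) & !is.na(fr$female_age)
  fr <- fr[keep & stats::complete.cases(fr), , drop = FALSE]
  rownames(fr) <- NULL
  for (col in c("group_id", "attempt_id", "guard_id", "female_id"))
    fr[[col]] <- factor(fr[[col]])
  attr(fr, "model_spec") <- list(
    response = "success", family = "binomial",
    fixed = c("guard_female_r", "male_age_rank", "female_age", "sex_ratio",
              "n_days_guarding"),
    random = c("group_id", "attempt_id", "guard_id", "female_id"))
  fr
}

# --- fitting and simplification --------------------------------------------

mixed_formula <- function(response, fixed, random) {
  rhs <- c(if (length(fixed)) fixed else "1",
           sprintf("(1 | %s)", random))
  stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
}

fit_mixed <- function(frame, response, fixed, random, family) {
  form <- mixed_formula(response, fixed, random)
  warn <- character(0)
  fit <- withCallingHandlers(
    if (family == "gaussian")
      lme4::lmer(form, data = frame, REML = FALSE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore"))
    else
      lme4::glmer(form, data = frame, family = stats::binomial(),
                  control = lme4::glmerControl(calc.derivs = FALSE,
                                               check.conv.singular = "ignore")),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  list(fit = fit, warnings = warn,
       converged = !any(grepl("failed to converge", warn, ignore.case = TRUE)))
}

lrt_chisq <- function(full, reduced) {
  chi <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                       as.numeric(stats::logLik(reduced))))
  c(chisq = chi, p = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Fit a mixed model and simplify it by backward elimination
#'
#' Fits the frame's model (maximum likelihood, so that likelihood-ratio
#' comparisons of fixed effects are valid) and sequentially drops the least
#' significant fixed effect until only terms with P < `alpha` remain. Each
#' eliminated term is then individually returned to the minimal model to
#' report its effect size (with SE) and likelihood-ratio chi-square against
#' the minimal model; retained terms are reported from the minimal model with
#' the chi-square for dropping them from it.
#'
#' @param frame a model frame from one of the `build_*_frame()` builders (or
#'   any data.frame with a `model_spec` attribute)
#' @param family `"gaussian"` or `"binomial"` (logit); defaults to the
#'   frame's spec
#' @param fixed,random,response override the frame's spec
#' @param alpha retention threshold (default 0.05)
#' @param eliminate if `FALSE`, skip backward elimination and report every
#'   term from the full model (each likelihood-ratio chi-square then compares
#'   the full model with the full model minus that term)
#' @param lrt if `FALSE` (only with `eliminate = FALSE`), report estimates and
#'   SEs from the single full-model fit and skip the per-term likelihood-ratio
#'   tests (`chisq` and `p` are `NA`)
#' @return a `model_fit_result`: list with `terms` (data.frame: `term`,
#'   `estimate`, `se`, `chisq`, `p`, `retained`), `intercept`,
#'   `random_effect_names`, `n_observations`, `converged`, `singular`,
#'   `minimal_model` (the fitted lme4 object)
#' @export
fit_and_simplify <- function(frame, family = NULL, fixed = NULL,
                             random = NULL, response = NULL, alpha = 0.05,
                             eliminate = TRUE, lrt = TRUE) {
  spec <- attr(frame, "model_spec")
  family <- family %||% spec$family
  fixed <- fixed %||% spec$fixed
  random <- random %||% spec$random
  response <- response %||% spec$response
  if (is.null(family) || is.null(random) || is.null(response))
    stop("frame has no model_spec; supply family/fixed/random/response")
  if (!nrow(frame)) stop("empty model frame")

  # fits are cached per term set: the elimination path and the reporting
  # phase ask for several identical reduced models
  cache <- new.env(parent = emptyenv())
  get_fit <- function(terms) {
    key <- paste0("k:", paste(sort(terms), collapse = "|"))
    if (is.null(cache[[key]]))
      cache[[key]] <- fit_mixed(frame, response, terms, random, family)
    cache[[key]]
  }

  current <- fixed
  dropped <- character(0)
  halted <- FALSE
  cur_fit <- get_fit(current)
  converged <- cur_fit$converged

  if (!eliminate && !lrt) {
    co <- summary(cur_fit$fit)$coefficients
    terms_tab <- data.frame(term = fixed, estimate = co[fixed, 1],
                            se = co[fixed, 2], chisq = NA_real_, p = NA_real_,
                            retained = TRUE)
    rownames(terms_tab) <- NULL
    return(structure(list(terms = terms_tab,
                          intercept = unname(co["(Intercept)", 1:2]),
                          random_effect_names = random,
                          n_observations = nrow(frame), family = family,
                          converged = converged,
                          singular = lme4::isSingular(cur_fit$fit),
                          retained = fixed, minimal_model = cur_fit$fit),
                     class = "model_fit_result"))
  }

  repeat {
    if (!eliminate || !length(current)) break
    stats_tab <- t(vapply(current, function(tm) {
      red <- tryCatch(get_fit(setdiff(current, tm)), error = function(e) NULL)
      if (is.null(red)) return(c(chisq = NA_real_, p = NA_real_))
      lrt_chisq(cur_fit$fit, red$fit)
    }, c(chisq = 0, p = 0)))
    if (anyNA(stats_tab[, "p"])) {
      halted <- TRUE
      converged <- FALSE
      break
    }
    worst <- which.max(stats_tab[, "p"])
    if (stats_tab[worst, "p"] < alpha) break
    dropped <- c(dropped, current[worst])
    current <- current[-worst]
    cur_fit <- get_fit(current)
    converged <- converged && cur_fit$converged
  }

  minimal <- cur_fit
  # per-term reporting against the minimal model
  rows <- list()
  for (tm in current) {
    red <- get_fit(setdiff(current, tm))
    lr <- lrt_chisq(minimal$fit, red$fit)
    co <- summary(minimal$fit)$coefficients
    rows[[tm]] <- data.frame(term = tm, estimate = co[tm, 1], se = co[tm, 2],
                             chisq = lr[["chisq"]], p = lr[["p"]],
                             retained = TRUE)
  }
  if (!halted) for (tm in dropped) {
    aug <- get_fit(c(current, tm))
    lr <- lrt_chisq(aug$fit, minimal$fit)
    co <- summary(aug$fit)$coefficients
    rows[[tm]] <- data.frame(term = tm, estimate = co[tm, 1], se = co[tm, 2],
                             chisq = lr[["chisq"]], p = lr[["p"]],
                             retained = FALSE)
  }
  terms_tab <- do.call(rbind, rows[fixed[fixed %in% names(rows)]])
  rownames(terms_tab) <- NULL
  co <- summary(minimal$fit)$coefficients

  structure(list(terms = terms_tab,
                 intercept = unname(co["(Intercept)", 1:2]),
                 random_effect_names = random,
                 n_observations = nrow(frame),
                 family = family,
                 converged = converged && !halted,
                 singular = lme4::isSingular(minimal$fit),
                 retained = current,
                 minimal_model = minimal$fit),
            class = "model_fit_result")
}

#' @export
print.model_fit_result <- function(x, ...) {
  cat(sprintf("model_fit_result (%s, n = %d%s%s)\n", x$family,
              x$n_observations,
              if (!x$converged) ", NOT converged" else "",
              if (x$singular) ", singular random effects" else ""))
  if (!is.null(x$terms)) {
    tab <- x$terms
    tab$estimate <- signif(tab$estimate, 4)
    tab$se <- signif(tab$se, 4)
    tab$chisq <- round(tab$chisq, 2)
    tab$p <- signif(tab$p, 3)
    print(tab, row.names = FALSE)
  }
  cat(sprintf("  intercept: %.4g +/- %.4g\n", x$intercept[1], x$intercept[2]))
  cat("  random effects:", paste(x$random_effect_names, collapse = ", "), "\n")
  invisible(x)
}

#' Write a model fit result to JSON
#'
#' @param result a `model_fit_result`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_model_result <- function(result, path) {
  x <- list(family = result$family,
            n_observations = result$n_observations,
            converged = result$converged,
            singular = result$singular,
            intercept = list(estimate = result$intercept[1],
                             se = result$intercept[2]),
            random_effects = result$random_effect_names,
            terms = result$terms)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
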