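#' Run the full inbreeding-avoidance pipeline from a config
#'
#' Orchestrates every stage in dependency order: data loading (from CSV paths
#' or the built-in simulator), pedigree validation and kinship, cohort
#' filters, the two permutation tests, the guard-success model, the paired
#' guard-vs-EPP comparisons and the inbreeding-depression models. Each
#' stage's result is written as JSON into the output directory together with
#' a consolidated Markdown report; a serialized copy of the config is written
#' before any stage runs. JSON outputs are deterministic given the same
#' config and inputs.
#'
#' @param config a named list, or path to a YAML file, with elements:
#'   \describe{
#'     \item{input}{either `list(paths = list(pedigree=, membership=, ...))`
#'       or `list(simulate = list(<sim_params arguments>))`}
#'     \item{analyses}{subset of `c("avoidance", "guarding", "guard_success",
#'       "epp", "depression")` (default: all)}
#'     \item{n_perms}{permutations for the randomization tests (default 10000)}
#'     \item{natal_only}{also run the natal-only variants (default FALSE)}
#'     \item{seed}{base seed; per-stage substreams are derived from it}
#'     \item{out_dir}{output directory}
#'     \item{maternal_age_unit}{`"months"` (default) or `"years"`}
#'   }
#' @return (invisibly) list with `results` (per analysis), `failed`
#'   (character vector of failed stages) and `out_dir`
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$input), !is.null(config$out_dir))
  analyses <- config$analyses %||%
    c("avoidance", "guarding", "guard_success", "epp", "depression")
  n_perms <- as.integer(config$n_perms %||% 10000L)
  natal_only <- isTRUE(config$natal_only)
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)

  failed <- character(0)
  results <- list()
  lines <- c("# Inbreeding-avoidance pipeline report", "")
  stage <- function(name, expr) {
    message("[stage] ", name)
    tryCatch(expr, error = function(e) {
      failed <<- c(failed, name)
      message("[stage] ", name, " FAILED: ", conditionMessage(e))
      NULL
    })
  }

  # --- load ---
  dataset <- if (!is.null(config$input$paths)) {
    read_study_tables(config$input$paths, config$input$column_map)
  } else if (!is.null(config$input$simulate)) {
    sp <- do.call(sim_params, c(config$input$simulate,
                                if (is.null(config$input$simulate$seed))
                                  list(seed = derive_seed(seed, "simulate"))))
    sim <- simulate_population(sp)
    jsonlite::write_json(sim$truth[setdiff(names(sim$truth), "pup_F")],
                         file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    write_study_tables(sim$dataset, file.path(out_dir, "tables"))
    sim$dataset
  } else stop("config$input must provide $paths or $simulate")

  ped <- dataset$pedigree
  A <- relatedness_matrix(ped)
  Ftab <- inbreeding(ped, A / 2)
  utils::write.csv(Ftab, file.path(out_dir, "inbreeding.csv"),
                   row.names = FALSE)
  lines <- c(lines, sprintf("- Pedigree: %d individuals, %d with both parents known, max F = %.4f",
                            nrow(ped), sum(Ftab$parents_known), max(Ftab$F)), "")

  variants <- if (natal_only) c(FALSE, TRUE) else FALSE

  if ("avoidance" %in% analyses) {
    lines <- c(lines, "## Breeding-pair relatedness vs random within-group mating", "")
    for (nat in variants) {
      tag <- if (nat) "avoidance_natal" else "avoidance"
      res <- stage(tag, {
        fl <- breeding_pair_filter(dataset, A, natal_only = nat)
        write_filter_report(fl$report, file.path(out_dir, paste0(tag, "_filter.json")))
        pt <- permutation_test(fl$dyads, dataset, A, type = "breeding",
                               n_perms = n_perms,
                               seed = derive_seed(seed, tag),
                               analysis_name = tag)
        write_permutation_result(pt, file.path(out_dir, paste0(tag, ".json")))
        pt
      })
      results[[tag]] <- res
      if (!is.null(res))
        lines <- c(lines, sprintf(
          "- %s: observed mean r = %.4f, null mean = %.4f, one-tailed P = %.4g (n = %d dyads)",
          tag, res$observed_mean, mean(res$null_means), res$p_one_tailed,
          res$n_dyads))
    }
    lines <- c(lines, "")
  }

  if ("guarding" %in% analyses) {
    lines <- c(lines, "## Guard-female relatedness vs random within-event guarding", "")
    for (nat in variants) {
      tag <- if (nat) "guarding_natal" else "guarding"
      res <- stage(tag, {
        fl <- guard_pair_filter(dataset, A, natal_only = nat)
        write_filter_report(fl$report, file.path(out_dir, paste0(tag, "_filter.json")))
        pt <- permutation_test(fl$dyads, dataset, A, type = "guard",
                               n_perms = n_perms,
                               seed = derive_seed(seed, tag),
                               analysis_name = tag)
        write_permutation_result(pt, file.path(out_dir, paste0(tag, ".json")))
        pt
      })
      results[[tag]] <- res
      if (!is.null(res))
        lines <- c(lines, sprintf(
          "- %s: observed mean r = %.4f, null mean = %.4f, one-tailed P = %.4g (n = %d dyads)",
          tag, res$observed_mean, mean(res$null_means), res$p_one_tailed,
          res$n_dyads))
    }
    lines <- c(lines, "")
  }

  if ("guard_success" %in% analyses) {
    lines <- c(lines, "## Mate-guard success vs guard-female relatedness", "")
    for (nat in variants) {
      tag <- if (nat) "guard_success_natal" else "guard_success"
      res <- stage(tag, {
        fr <- build_guard_success_frame(dataset, A, natal_only = nat)
        fit <- fit_and_simplify(fr)
        write_model_result(fit, file.path(out_dir, paste0(tag, ".json")))
        fit
      })
      results[[tag]] <- res
      if (!is.null(res))
        lines <- c(lines, sprintf("- %s: n = %d, retained terms: %s", tag,
                                  res$n_observations,
                                  if (length(res$retained))
                                    paste(res$retained, collapse = ", ")
                                  else "none"))
    }
    lines <- c(lines, "")
  }

  if ("epp" %in% analyses) {
    lines <- c(lines, "## Guard vs extra-pair sire relatedness (paired)", "")
    for (nat in variants) {
      tag <- if (nat) "epp_natal" else "epp"
      res <- stage(tag, {
        ep <- identify_epp(dataset, A, natal_only = nat)
        write_filter_report(ep$report, file.path(out_dir, paste0(tag, "_filter.json")))
        scopes <- c("all", "within_group", "extra_group")
        tests <- lapply(scopes, function(sc)
          tryCatch(epp_comparison(ep$pairs, sc), error = function(e) NULL))
        names(tests) <- scopes
        keepers <- !vapply(tests, is.null, TRUE)
        jsonlite::write_json(
          lapply(tests[keepers], function(tt)
            tt[c("scope", "n_pairs", "mean_difference", "t_statistic",
                 "degrees_of_freedom", "p_two_tailed")]),
          file.path(out_dir, paste0(tag, ".json")),
          auto_unbox = TRUE, pretty = TRUE, digits = NA)
        tests
      })
      results[[tag]] <- res
      if (!is.null(res)) for (sc in names(res)) if (!is.null(res[[sc]]))
        lines <- c(lines, sprintf(
          "- %s [%s]: mean(guard_r - epp_r) = %.4f, t(%d) = %.3f, P = %.4g",
          tag, sc, res[[sc]]$mean_difference, res[[sc]]$degrees_of_freedom,
          res[[sc]]$t_statistic, res[[sc]]$p_two_tailed))
    }
    lines <- c(lines, "")
  }

  if ("depression" %in% analyses) {
    lines <- c(lines, "## Inbreeding depression (yearling mass; survival to 1 yr)", "")
    unit <- config$maternal_age_unit %||% "months"
    for (resp in c("mass", "survival")) {
      tag <- paste0("depression_", resp)
      res <- stage(tag, {
        fr <- if (resp == "mass")
          build_mass_frame(dataset, Ftab, maternal_age_unit = unit)
        else build_survival_frame(dataset, Ftab, maternal_age_unit = unit)
        fit <- fit_and_simplify(fr)
        write_model_result(fit, file.path(out_dir, paste0(tag, ".json")))
        fit
      })
      results[[tag]] <- res
      if (!is.null(res)) {
        frow <- res$terms[res$terms$term == "F", , drop = FALSE]
        lines <- c(lines, sprintf(
          "- %s: n = %d; F effect %.2f +/- %.2f (chi-sq = %.2f, P = %.3g, %s)",
          tag, res$n_observations, frow$estimate, frow$se, frow$chisq, frow$p,
          if (frow$retained) "retained" else "dropped"))
      }
    }
    lines <- c(lines, "")
  }

  if (length(failed))
    lines <- c(lines, "## Failed stages", "", paste("-", failed), "")
  writeLines(lines, file.path(out_dir, "report.md"))
  invisible(list(results = results, failed = failed, out_dir = out_dir))
}

#' Histogram of a permutation null distribution
#'
#' Base-graphics histogram of the null means with the observed mean marked.
#'
#' @param result a `permutation_result`
#' @param ... passed to [graphics::hist()]
#' @return invisibly, the histogram object
#' @export
plot_null_distribution <- function(result, ...) {
  h <- graphics::hist(result$null_means,
                      main = result$analysis_name,
                      xlab = "null mean pairwise relatedness",
                      xlim = range(c(result$null_means, result$observed_mean)),
                      ...)
  graphics::abline(v = result$observed_mean, lwd = 2)
  invisible(h)
}
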