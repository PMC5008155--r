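#' Paired t-test on relatedness differences
#'
#' Tests whether the mean of paired differences (here guard-female relatedness
#' minus EPP-male-female relatedness) differs from zero:
#' t = mean(d) / (sd(d) / sqrt(n)) on n - 1 degrees of freedom, with the
#' two-tailed P from the t distribution.
#'
#' @param differences numeric vector of paired differences (n >= 2)
#' @return a `paired_test_result`: list with `n_pairs`, `mean_difference`,
#'   `t_statistic`, `degrees_of_freedom`, `p_two_tailed`
#' @export
paired_t <- function(differences) {
  d <- differences[!is.na(differences)]
  n <- length(d)
  if (n < 2L) stop("need at least 2 paired differences")
  s <- stats::sd(d)
  if (s == 0) stop("zero variance in paired differences")
  t_stat <- mean(d) / (s / sqrt(n))
  structure(list(n_pairs = n,
                 mean_difference = mean(d),
                 t_statistic = t_stat,
                 degrees_of_freedom = n - 1L,
                 p_two_tailed = 2 * stats::pt(-abs(t_stat), df = n - 1L)),
            class = "paired_test_result")
}

#' Guard-versus-EPP relatedness comparison
#'
#' Paired t-test of guard_r - epp_r over the paired rows from
#' [identify_epp()], optionally limited to within-group or extra-group EPP
#' males. A positive mean difference means females are less related to the
#' extra-pair sire than to their mate-guard.
#'
#' @param pairs data.frame from `identify_epp()$pairs`
#' @param scope `"all"`, `"within_group"` or `"extra_group"`
#' @return a `paired_test_result` (with the scope and n recorded)
#' @export
epp_comparison <- function(pairs, scope = c("all", "within_group", "extra_group")) {
  scope <- match.arg(scope)
  if (scope != "all")
    pairs <- pairs[pairs$epp_scope == scope, , drop = FALSE]
  if (nrow(pairs) < 2L)
    stop("fewer than 2 paired rows in scope '", scope, "'")
  res <- paired_t(pairs$guard_r - pairs$epp_r)
  res$scope <- scope
  res
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf(paste0("paired_test_result%s: mean difference = %.4f, ",
                     "t(%d) = %.3f, two-tailed P = %.4g (n = %d)\n"),
              if (!is.null(x$scope)) paste0(" [", x$scope, "]") else "",
              x$mean_difference, x$degrees_of_freedom, x$t_statistic,
              x$p_two_tailed, x$n_pairs))
  invisible(x)
}
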