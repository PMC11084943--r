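#' Test-result container
#'
#' Every inferential routine of the package returns a `dm_test`: the named
#' statistic, its value, the p-value, the per-group sample sizes and a
#' method-details list (tails, permutation count, seed where applicable).
#'
#' @param statistic_name,statistic,p_value,n_per_group,method,details
#'   Components of the result.
#' @return An object of class `dm_test`.
#' @keywords internal
new_dm_test <- function(statistic_name, statistic, p_value, n_per_group,
                        method, details = list()) {
  stopifnot(is.finite(p_value), p_value >= 0, p_value <= 1)
  structure(list(statistic_name = statistic_name,
                 statistic = unname(statistic), p_value = unname(p_value),
                 n_per_group = n_per_group, method = method,
                 details = details),
            class = "dm_test")
}

#' @export
print.dm_test <- function(x, ...) {
  cat(sprintf("%s: %s = %.4g, p = %.4g (n = %s)\n", x$method,
              x$statistic_name, x$statistic, x$p_value,
              paste(x$n_per_group, collapse = "/")))
  invisible(x)
}

#' Exact Fisher test for a 2x2 table
#'
#' Full hypergeometric enumeration. The two-sided p-value follows the
#' point-probability rule: the sum of the probabilities of all tables with
#' the same margins whose probability does not exceed that of the observed
#' table (within a relative tolerance of 1e-7, the usual convention).
#' One-sided tails sum the upper (`"greater"`, enrichment of cell `[1,1]`)
#' or lower (`"less"`) tail of the hypergeometric distribution.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param tail `"two.sided"`, `"greater"` or `"less"`.
#' @return A [`dm_test`][new_dm_test] with the sample odds ratio as
#'   statistic.
#' @examples
#' fisher_exact(matrix(c(49, 39, 3, 9), 2))
#' @export
fisher_exact <- function(table, tail = c("two.sided", "greater", "less")) {
  tail <- match.arg(tail)
  tb <- as.matrix(table)
  if (!all(dim(tb) == c(2L, 2L))) stop("a 2x2 table is required")
  if (any(tb < 0) || any(tb != round(tb))) stop("counts must be non-negative integers")
  if (any(rowSums(tb) == 0) || any(colSums(tb) == 0))
    stop("all margins must be positive")

  a <- tb[1, 1]
  m <- sum(tb[1, ])            # row-1 total ("white balls")
  n2 <- sum(tb[2, ])           # row-2 total
  k <- sum(tb[, 1])            # column-1 total (draws)
  support <- max(0, k - n2):min(k, m)
  dens <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)

  p <- switch(tail,
    two.sided = sum(dens[dens <= p_obs * (1 + 1e-7)]),
    greater = sum(dens[support >= a]),
    less = sum(dens[support <= a]))
  p <- min(1, p)
  or <- (tb[1, 1] * tb[2, 2]) / (tb[1, 2] * tb[2, 1])
  new_dm_test("odds_ratio", or, p, n_per_group = rowSums(tb),
              method = "Fisher's exact test",
              details = list(tail = tail, table = tb))
}

#' Rank-based two-sample, k-sample and one-sample tests
#'
#' Thin contracts over the standard rank tests: `rank_sum()` is the
#' Wilcoxon/Mann-Whitney rank-sum test (statistic W), `kruskal()` the
#' Kruskal-Wallis test (statistic H, chi-squared approximation) and
#' `signed_rank_vs()` the Wilcoxon signed-rank test of a sample against a
#' theoretical value (statistic V), used e.g. for the short-term memory
#' ratio against 1 or an odor preference against 50%. Ties are handled by
#' mid-ranks; exact small-sample p-values are used when possible, otherwise
#' the normal approximation with continuity correction.
#'
#' @param x,y Numeric samples.
#' @param groups A list of numeric samples (or a factor-split data set).
#' @param mu Theoretical value to test against.
#' @param tail `"two.sided"`, `"greater"` or `"less"`.
#' @return A [`dm_test`][new_dm_test].
#' @export
rank_sum <- function(x, y, tail = c("two.sided", "greater", "less")) {
  tail <- match.arg(tail)
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = tail))
  new_dm_test("W", wt$statistic, wt$p.value,
              n_per_group = c(length(x), length(y)),
              method = "Wilcoxon rank sum test",
              details = list(tail = tail))
}

#' @rdname rank_sum
#' @export
kruskal <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  kt <- stats::kruskal.test(groups)
  new_dm_test("chi-squared", kt$statistic, kt$p.value,
              n_per_group = lengths(groups),
              method = "Kruskal-Wallis rank sum test",
              details = list(df = unname(kt$parameter)))
}

#' @rdname rank_sum
#' @export
signed_rank_vs <- function(x, mu, tail = c("two.sided", "greater", "less")) {
  tail <- match.arg(tail)
  stopifnot(length(x) >= 2L)
  if (all(x == mu)) stop("all differences are zero")
  wt <- suppressWarnings(stats::wilcox.test(x, mu = mu, alternative = tail))
  new_dm_test("V", wt$statistic, wt$p.value, n_per_group = length(x),
              method = "Wilcoxon signed rank test",
              details = list(tail = tail, mu = mu))
}
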