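#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Thin, validated wrapper around [stats::fisher.test()]. The two-sided
#' p-value is the sum over all tables with the observed margins whose point
#' hypergeometric probability does not exceed the observed one (up to a
#' relative tolerance of 1e-7, R's convention).
#'
#' @param table 2x2 matrix of non-negative integer counts, or a length-4
#'   vector `c(a, b, c, d)` filled row-wise.
#' @return List with `p` (two-sided p-value), `odds_ratio` (conditional MLE,
#'   informational) and `table`.
#' @export
fisher_exact <- function(table) {
  tab <- as_2x2(table)
  if (any(tab < 0)) stop("contingency table cells must be non-negative")
  if (sum(tab) == 0) stop("contingency table must have at least one positive margin")
  ft <- stats::fisher.test(tab)
  list(p = ft$p.value, odds_ratio = unname(ft$estimate), table = tab,
       method = "fisher.exact.two.sided")
}

as_2x2 <- function(x) {
  if (is.matrix(x)) {
    if (!all(dim(x) == c(2L, 2L))) stop("expected a 2x2 table")
    tab <- x
  } else {
    if (length(x) != 4L) stop("expected a 2x2 table")
    tab <- matrix(as.numeric(x), 2L, 2L, byrow = TRUE)
  }
  if (any(tab != round(tab))) stop("contingency table cells must be integers")
  storage.mode(tab) <- "double"
  tab
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Mid-ranks are used for ties. The p-value is exact (by enumeration of rank
#' assignments, as in [stats::wilcox.test()]) when the combined sample size is
#' at most `exact_max` and there are no ties; otherwise the normal
#' approximation with tie and continuity correction is used.
#'
#' @param a,b Numeric samples, both non-empty.
#' @param exact_max Largest combined sample size for which the exact
#'   distribution is used (default 12).
#' @return List with `statistic` (W, rank-sum form of sample `a`), `p`
#'   (two-sided), `method`, and `degenerate` (TRUE when all values are equal
#'   across both samples, in which case p = 1).
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max = 12L) {
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be non-empty")
  if (length(unique(c(a, b))) == 1L) {
    return(list(statistic = NA_real_, p = 1, method = "wilcoxon.degenerate",
                degenerate = TRUE))
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- (length(a) + length(b)) <= exact_max && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p = wt$p.value,
       method = if (use_exact) "wilcoxon.exact" else "wilcoxon.normal.approx",
       degenerate = FALSE)
}

#' Kruskal-Wallis rank test across two or more groups
#'
#' Tie-corrected H statistic with the chi-square approximation on
#' `length(groups) - 1` degrees of freedom.
#'
#' @param groups List of (at least two) non-empty numeric vectors.
#' @return List with `statistic` (H), `df`, `p`, and `degenerate` (TRUE when
#'   every value is identical, in which case H = 0 and p = 1).
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups")
  if (any(lengths(groups) == 0L)) stop("every group must be non-empty")
  if (length(unique(unlist(groups))) == 1L) {
    return(list(statistic = 0, df = length(groups) - 1L, p = 1,
                degenerate = TRUE))
  }
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, degenerate = FALSE)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up procedure via [stats::p.adjust()]; preserves input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' Probability of drawing at least `k` annotated items in a sample of `n`
#' from a universe of `N` containing `K` annotated items.
#'
#' @param k,n,K,N Non-negative integers with `k <= min(n, K)` and `n, K <= N`.
#' @return Upper-tail probability.
#' @export
hypergeometric_upper <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || n > N || K > N)
    stop("invalid hypergeometric parameters")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}
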