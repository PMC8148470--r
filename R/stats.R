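#' Mann-Whitney (Wilcoxon rank-sum) comparison of two groups
#'
#' U is computed from midrank sums. The two-sided p-value is exact (full
#' enumeration of the rank-sum distribution) when the combined sample size
#' is at most 12 and there are no ties -- matching the small per-group sizes
#' typical of in-vivo experiments -- and otherwise uses the normal
#' approximation with tie and continuity corrections. The method used is
#' recorded.
#'
#' @param a,b Numeric vectors, each non-empty.
#' @return An object of class `group_comparison`: list with `n_a`, `n_b`,
#'   `u_statistic`, `p_value`, `method` ("exact" or "normal-approx").
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1L || length(b) < 1L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  n_a <- length(a); n_b <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (n_a + n_b) <= 12L && !ties
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE, alternative = "two.sided")
  )
  structure(list(n_a = n_a, n_b = n_b, u_statistic = u,
                 p_value = min(1, wt$p.value),
                 method = if (exact) "exact" else "normal-approx"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney: U = %g, p = %g (%s; n = %d vs %d)\n",
              x$u_statistic, x$p_value, x$method, x$n_a, x$n_b))
  invisible(x)
}

#' Kruskal-Wallis comparison across groups
#'
#' Midrank-tie-corrected H statistic with a chi-square upper-tail p-value on
#' k - 1 degrees of freedom. When every observation is identical the
#' statistic is undefined; the result is then flagged degenerate rather than
#' propagating NaN.
#'
#' @param groups List of at least two non-empty numeric vectors.
#' @return List with `h_statistic`, `p_value`, `df`, `degenerate`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("`groups` must be a list of >= 2 groups", call. = FALSE)
  }
  if (any(vapply(groups, length, integer(1)) < 1L)) {
    stop("every group must be non-empty", call. = FALSE)
  }
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1L) {
    return(list(h_statistic = NA_real_, p_value = NA_real_,
                df = length(groups) - 1L, degenerate = TRUE))
  }
  kt <- kruskal.test(groups)
  list(h_statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter), degenerate = FALSE)
}

#' qRT-PCR expression ratio (GOI over normalizers)
#'
#' The expression ratio of a gene of interest relative to housekeeping
#' normalizers from cycle-threshold values:
#' `2^(-mean(ct_goi)) / 2^(-mean(ct_nor)) = 2^(mean(ct_nor) - mean(ct_goi))`.
#' When several normalizer genes are used (e.g. GAPDH and snU6), their Ct
#' values are pooled into a single mean before the formula.
#'
#' @param ct_goi Numeric Ct cycles of the gene of interest.
#' @param ct_nor Numeric Ct cycles of the normalizer gene(s), pooled.
#' @return List with `ct_goi`, `ct_nor`, `ratio` (> 0).
#' @examples
#' expression_ratio(20, 18)$ratio  # 0.25
#' @export
expression_ratio <- function(ct_goi, ct_nor) {
  ct_goi <- as.numeric(ct_goi); ct_nor <- as.numeric(ct_nor)
  if (length(ct_goi) < 1L || length(ct_nor) < 1L) {
    stop("both Ct lists must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(ct_goi)) || any(!is.finite(ct_nor))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  list(ct_goi = ct_goi, ct_nor = ct_nor,
       ratio = 2^(mean(ct_nor) - mean(ct_goi)))
}
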