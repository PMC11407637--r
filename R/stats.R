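#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; `NA`s are preserved and excluded
#' from the family size.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  # tolerate floating-point overshoot from upstream exact tests
  eps <- 1e-8
  if (any(pvalues[ok] < -eps | pvalues[ok] > 1 + eps))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pmin(pmax(pvalues, 0), 1), method = "BH")
}

#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum test; exact p-value when both samples are small and
#' tie-free (delegating the exact/approximate switch at `exact_max` to the
#' underlying machinery), otherwise normal approximation with tie and
#' continuity correction.
#'
#' @param x,y numeric samples (n >= 3 each recommended).
#' @param two_sided two-sided alternative (default `TRUE`).
#' @param exact_max use the exact distribution when `min(n) <= exact_max` and
#'   there are no ties (default 8).
#' @return list: `statistic` (W), `pvalue`, `n_x`, `n_y`, `method`,
#'   `all_tied` flag.
#' @export
rank_sum_test <- function(x, y, two_sided = TRUE, exact_max = 8L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  alt <- if (two_sided) "two.sided" else "greater"
  if (length(unique(c(x, y))) == 1L)
    return(list(statistic = length(x) * length(y) / 2, pvalue = 1,
                n_x = length(x), n_y = length(y),
                method = "degenerate", all_tied = TRUE))
  ties <- any(duplicated(c(x, y)))
  exact <- !ties && min(length(x), length(y)) <= exact_max
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alt,
                                            exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), pvalue = wt$p.value,
       n_x = length(x), n_y = length(y),
       method = if (exact) "exact" else "normal-approx", all_tied = FALSE)
}

#' Pairwise tests on 2 x k contingency tables
#'
#' Fisher's exact test for 2 x 2 tables, chi-squared otherwise; chi-squared
#' falls back to Fisher when any expected count is below 1. P-values are
#' BH-adjusted across the family of pairs.
#'
#' @param tables named list of matrices (2 rows x k columns, counts).
#' @param method `"fisher"` or `"chi2"`.
#' @return `data.table`: `comparison`, `method`, `statistic` (NA for Fisher),
#'   `pvalue`, `padj`.
#' @export
pairwise_count_tests <- function(tables, method = c("fisher", "chi2")) {
  method <- match.arg(method)
  res <- data.table::rbindlist(lapply(names(tables), function(nm) {
    tab <- as.matrix(tables[[nm]])
    m <- method
    if (m == "chi2") {
      expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expd < 1)) m <- "fisher"
    }
    if (m == "fisher") {
      ft <- stats::fisher.test(tab)
      data.table::data.table(comparison = nm, method = "fisher",
                             statistic = NA_real_,
                             pvalue = min(1, ft$p.value))
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      data.table::data.table(comparison = nm, method = "chi2",
                             statistic = unname(ct$statistic),
                             pvalue = ct$p.value)
    }
  }))
  res[, padj := bh_adjust(pvalue)]
  res[]
}

#' Spearman rank correlation
#'
#' Average ranks for ties; p-value by the exact permutation distribution for
#' small tie-free samples (n <= 10) and the t-approximation otherwise.
#'
#' @param x,y numeric vectors (n >= 3).
#' @return list: `rho`, `pvalue`, `n`, `undefined` (zero rank variance).
#' @export
spearman <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("spearman requires n >= 3")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(rho = NA_real_, pvalue = NA_real_, n = n, undefined = TRUE))
  ties <- any(duplicated(x)) || any(duplicated(y))
  exact <- !ties && n <= 10
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = exact))
  list(rho = unname(ct$estimate), pvalue = ct$p.value, n = n, undefined = FALSE)
}

#' Unpaired two-sample t-test
#'
#' Welch's unequal-variance variant by default; pooled-variance Student's test
#' on request. Two-sided.
#'
#' @param x,y numeric samples (n >= 2 each).
#' @param pooled use the pooled-variance variant (default `FALSE` = Welch).
#' @return list: `statistic`, `pvalue`, `df`, `n_x`, `n_y`, `method`.
#' @export
unpaired_t <- function(x, y, pooled = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("unpaired_t requires n >= 2 per group")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(list(statistic = 0, pvalue = 1, df = NA_real_,
                  n_x = length(x), n_y = length(y), method = "degenerate"))
  }
  tt <- stats::t.test(x, y, var.equal = pooled)
  list(statistic = unname(tt$statistic), pvalue = tt$p.value,
       df = unname(tt$parameter), n_x = length(x), n_y = length(y),
       method = if (pooled) "pooled" else "welch")
}
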