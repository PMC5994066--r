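#' @title Core statistical tests
#' @description Thin, uniformly-shaped wrappers around the exact and
#'   rank-based tests used throughout the pipeline. Every wrapper returns a
#'   one-row tibble (`statistic`, `p_value`, `method`, `n`, `alternative`,
#'   `note`) so downstream modules can bind results into report tables.
#' @name stats_core
NULL

test_result <- function(statistic, p_value, method, n, alternative = "two.sided",
                        note = NA_character_) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  tibble::tibble(
    statistic = as.numeric(statistic), p_value = as.numeric(p_value),
    method = method, n = paste(n, collapse = ","),
    alternative = alternative, note = note
  )
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p is the sum of hypergeometric probabilities, over all tables
#' with the observed margins, that do not exceed the probability of the
#' observed table ("probability <= observed" convention). One-sided p is
#' the corresponding tail sum.
#'
#' @param a,b,c,d Cell counts, row-wise: `(a, b)` over `(c, d)`.
#' @param alternative `"two.sided"`, `"greater"`, or `"less"`.
#' @return One-row test-result tibble.
#' @export
fisher_exact_2x2 <- function(a, b, c, d, alternative = "two.sided") {
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  if (sum(cells) == 0) stop("all-zero 2x2 table")
  tab <- matrix(cells, 2, 2, byrow = TRUE)
  ft <- stats::fisher.test(tab, alternative = alternative)
  test_result(
    statistic = unname(ft$estimate), p_value = ft$p.value,
    method = "fisher_exact", n = sum(cells), alternative = alternative
  )
}

#' Pearson chi-square test on an r x c table
#'
#' Pearson statistic with expected counts from the margins and p from the
#' chi-square distribution on (r-1)(c-1) degrees of freedom; no continuity
#' correction.
#'
#' @param tab Matrix of nonnegative counts, at least 2x2.
#' @return One-row test-result tibble.
#' @export
chi_square_rxc <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) >= 2, ncol(tab) >= 2, all(tab >= 0))
  if (sum(tab) == 0) stop("empty contingency table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("contingency table has a zero margin")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  test_result(
    statistic = unname(ct$statistic), p_value = ct$p.value,
    method = "chi_square", n = sum(tab)
  )
}

#' Two-sample location tests
#'
#' Dispatches to the paired and unpaired tests used across the analysis.
#' Paired modes drop pairs with missing values; if every paired difference
#' is zero the test is degenerate and p = 1 is reported with a warning.
#' The Mann-Whitney test is exact for combined n <= 20 without ties and
#' uses the tie-corrected normal approximation otherwise.
#'
#' @param x Numeric vector (or, for `kruskal_wallis`, all values).
#' @param y Second numeric vector (for `kruskal_wallis`, a grouping factor
#'   aligned with `x`).
#' @param mode One of `"wilcoxon_signed_rank"`, `"mann_whitney"`,
#'   `"welch_t"`, `"paired_t"`, `"kruskal_wallis"`.
#' @param alternative Test sidedness (ignored by `kruskal_wallis`).
#' @return One-row test-result tibble.
#' @export
two_sample_test <- function(x, y,
                            mode = c(
                              "wilcoxon_signed_rank", "mann_whitney",
                              "welch_t", "paired_t", "kruskal_wallis"
                            ),
                            alternative = "two.sided") {
  mode <- match.arg(mode)
  if (mode %in% c("wilcoxon_signed_rank", "paired_t")) {
    stopifnot(length(x) == length(y))
    keep <- stats::complete.cases(x, y)
    x <- x[keep]
    y <- y[keep]
    if (all(x == y)) {
      warning("all paired differences are zero; degenerate test, p = 1")
      return(test_result(0, 1,
        method = mode, n = length(x),
        alternative = alternative, note = "degenerate: zero differences"
      ))
    }
  } else if (mode != "kruskal_wallis") {
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
  }
  res <- switch(mode,
    wilcoxon_signed_rank = suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE, alternative = alternative)
    ),
    mann_whitney = {
      ties <- anyDuplicated(c(x, y)) > 0
      suppressWarnings(stats::wilcox.test(x, y,
        alternative = alternative,
        exact = (length(x) + length(y) <= 20) && !ties, correct = ties
      ))
    },
    welch_t = stats::t.test(x, y, alternative = alternative, var.equal = FALSE),
    paired_t = stats::t.test(x, y, paired = TRUE, alternative = alternative),
    kruskal_wallis = {
      stopifnot(length(unique(y[!is.na(x)])) >= 2)
      stats::kruskal.test(x, as.factor(y))
    }
  )
  n <- if (mode == "kruskal_wallis") sum(!is.na(x)) else c(length(x), length(y))
  test_result(
    statistic = unname(res$statistic), p_value = res$p.value,
    method = mode, n = n,
    alternative = if (mode == "kruskal_wallis") "two.sided" else alternative
  )
}

#' Correlation tests
#'
#' Pearson or Spearman correlation on pairwise-complete observations.
#' Spearman uses mid-ranks for ties, with exact permutation p for n <= 9
#' and the t approximation otherwise. Zero variance in either vector makes
#' the coefficient undefined: the result is flagged (NA estimate), never
#' reported as 0.
#'
#' @param x,y Numeric vectors.
#' @param mode `"pearson"` or `"spearman"`.
#' @return One-row tibble with an `estimate` column added.
#' @export
correlation <- function(x, y, mode = c("pearson", "spearman")) {
  mode <- match.arg(mode)
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    out <- test_result(NA_real_, NA_real_,
      method = paste0(mode, "_correlation"),
      n = n, note = "degenerate: zero variance"
    )
    out$estimate <- NA_real_
    return(out)
  }
  ct <- suppressWarnings(stats::cor.test(x, y,
    method = mode,
    exact = if (mode == "spearman") n <= 9 else NULL
  ))
  out <- test_result(
    statistic = unname(ct$statistic), p_value = ct$p.value,
    method = paste0(mode, "_correlation"), n = n
  )
  out$estimate <- unname(ct$estimate)
  out
}

#' Benjamini-Hochberg step-up FDR correction
#'
#' Computes `q_i = min over j with p_(j) >= p_(i) of min(1, m * p_(j) / j)`
#' and flags results at `q <= q_threshold`. Output is returned in the input
#' order and is invariant to input permutation.
#'
#' @param p Vector of p values in `[0, 1]`.
#' @param q_threshold Significance threshold on q.
#' @return Tibble with columns `p`, `q`, `significant`.
#' @export
bh_fdr <- function(p, q_threshold = 0.10) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  q <- stats::p.adjust(p, method = "BH")
  tibble::tibble(p = p, q = q, significant = !is.na(q) & q <= q_threshold)
}
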