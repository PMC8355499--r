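# Statistical primitives shared by the analysis stages. These wrap the
# corresponding base-R tests behind a uniform tibble interface; each is
# verified against a closed form or enumeration oracle in the test suite.

test_row <- function(method, statistic = NA_real_, df = NA_real_,
                     p.value = NA_real_, estimate = NA_real_, note = NA_character_) {
  tibble(method = method, statistic = statistic, df = df,
         p.value = p.value, estimate = estimate, note = note)
}

#' Welch two-sample t test
#'
#' Unequal-variance t test with Welch-Satterthwaite degrees of freedom,
#' two-sided by default. Degenerate inputs (zero variance in both groups) are
#' resolved explicitly: equal means give `t = 0, p = 1`; unequal means give
#' an infinite statistic with `p = 0`, flagged in the `note` column.
#'
#' @param x,y Numeric vectors, each of length at least 2.
#' @param two_sided Two-sided p value (default) or one-sided (greater).
#' @return One-row tibble with `statistic`, `df`, `p.value` and `estimate`
#'   (mean of `x` minus mean of `y`).
#' @examples
#' welch_t_test(c(1, 2, 3), c(4, 5, 6))
#' @export
welch_t_test <- function(x, y, two_sided = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    abort("welch_t_test needs at least 2 observations per group")
  }
  est <- mean(x) - mean(y)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (est == 0) {
      return(test_row("Welch t-test", 0, NA_real_, 1, 0, "constant data"))
    }
    return(test_row("Welch t-test", sign(est) * Inf, NA_real_, 0, est,
                    "constant data, unequal means"))
  }
  alt <- if (two_sided) "two.sided" else "greater"
  tt <- stats::t.test(x, y, alternative = alt)
  test_row("Welch t-test", unname(tt$statistic), unname(tt$parameter),
           tt$p.value, est)
}

#' Rank or product-moment correlation test
#'
#' Spearman's rank correlation (with average ranks for ties and the t
#' approximation for the p value) or Pearson's correlation.
#'
#' @param x,y Paired numeric vectors, `n >= 3`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return One-row tibble; `estimate` is the correlation coefficient.
#' @export
rank_correlation <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("rank_correlation needs at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warn("zero variance: correlation undefined")
    return(test_row(paste0(method, " correlation")))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  test_row(paste0(method, " correlation"), unname(ct$statistic),
           if (!is.null(ct$parameter)) unname(ct$parameter) else NA_real_,
           ct$p.value, unname(ct$estimate))
}

#' Bonferroni significance threshold
#'
#' Family-wise error threshold `alpha / n_tests` used to call per-family and
#' per-site tests significant.
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param n_tests Number of tests (>= 1).
#' @return The per-test threshold.
#' @examples
#' bonferroni_threshold(0.05, 8402)
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false discovery rate adjustment. `NA` entries propagate as `NA`
#' and are excluded from the number of tests.
#'
#' @param p Vector of p values in \[0, 1\] (NA allowed).
#' @return Adjusted p values, clipped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) abort("p values must be in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p value under the "probability at most that of the observed
#' table" convention, with the conditional maximum-likelihood odds ratio. A
#' zero margin makes the test uninformative: `p = 1` with an undefined odds
#' ratio, flagged in `note`.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param two_sided Two-sided (default) or one-sided (greater) alternative.
#' @return One-row tibble; `estimate` is the conditional odds ratio.
#' @export
fisher_exact_2x2 <- function(table, two_sided = TRUE) {
  m <- as.matrix(table)
  stopifnot(all(dim(m) == c(2, 2)), all(m >= 0))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(test_row("Fisher exact test", p.value = 1,
                    note = "zero margin: odds ratio undefined"))
  }
  alt <- if (two_sided) "two.sided" else "greater"
  ft <- stats::fisher.test(m, alternative = alt)
  test_row("Fisher exact test", p.value = ft$p.value,
           estimate = unname(ft$estimate))
}

#' Pearson chi-square test for an r x c contingency table
#'
#' No continuity correction; degrees of freedom `(r - 1)(c - 1)`.
#'
#' @param table Matrix of counts; rows and columns must have positive sums.
#' @return One-row tibble with the chi-square statistic, df and p value.
#' @export
chi_square_contingency <- function(table) {
  m <- as.matrix(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("contingency table has a zero row or column sum")
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  test_row("Pearson chi-square", unname(ct$statistic), unname(ct$parameter),
           ct$p.value)
}

#' Arcsine square root transform of proportions
#'
#' The classical variance-stabilising transform for proportions,
#' `asin(sqrt(p))`, mapping \[0, 1\] monotonically onto \[0, pi/2\]. Used on
#' TE copy-number proportions and insertion frequencies before ANOVA.
#'
#' @param p Proportion(s) in \[0, 1\].
#' @return Transformed value(s).
#' @examples
#' arcsine_sqrt(0.25) # pi/6
#' @export
arcsine_sqrt <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("proportions must be in [0, 1]")
  }
  asin(sqrt(p))
}

#' All pairwise Welch t tests with Holm adjustment
#'
#' Compares every pair of groups with [welch_t_test()] and adjusts the p
#' values with Holm's step-down procedure. Serves as the post-hoc contrast
#' after a one-way ANOVA across studies.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, at least two groups of size >= 2.
#' @param adjust Adjustment method, `"holm"`.
#' @return Tibble with one row per pair: `group1`, `group2`, `statistic`,
#'   `df`, `p.value`, `p.adjusted`, `estimate`.
#' @export
pairwise_group_comparison <- function(values, groups, adjust = "holm") {
  adjust <- match.arg(adjust, "holm")
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) < 2) abort("need at least 2 groups")
  pairs <- utils::combn(lev, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    tt <- welch_t_test(values[groups == g1], values[groups == g2])
    tibble(group1 = g1, group2 = g2, statistic = tt$statistic, df = tt$df,
           p.value = tt$p.value, estimate = tt$estimate)
  })
  res$p.adjusted <- stats::p.adjust(res$p.value, method = adjust)
  res
}
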