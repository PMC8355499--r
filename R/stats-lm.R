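#' Fit a fixed-effects linear model with sequential ANOVA decomposition
#'
#' Fits an ordinary least-squares model and decomposes the variance with
#' sequential (type I) sums of squares in the order the terms appear in the
#' formula, testing every term against the residual mean square. This is the
#' classical `aov` idiom used throughout the abundance and frequency
#' analyses, e.g. `insertions ~ regime + regime/population` for replicate
#' populations nested within breeding regime, or
#' `freq_t ~ diet * regime` for diet-structured designs.
#'
#' Note that when per-position coverage values (or per-site frequencies) are
#' the response, positions within a population are treated as independent
#' observations; the pseudoreplication this implies is a deliberate property
#' of the analysis idiom, not an accident.
#'
#' @param data Data frame holding the response and factor columns.
#' @param formula Model formula; categorical terms are coerced to factors.
#' @return An object of class `te_lm` with a `terms` tibble (term, df,
#'   sumsq, meansq, statistic, p.value), residual df/SS, coefficients and the
#'   fit itself. `tidy()` and `glance()` methods are provided.
#' @examples
#' d <- data.frame(y = c(0, 1, 2, 3), a = c("a", "a", "b", "b"))
#' tidy(fit_fixed_lm(d, y ~ a))
#' @export
fit_fixed_lm <- function(data, formula) {
  df <- as.data.frame(data)
  vars <- all.vars(formula)
  response <- vars[1]
  for (v in vars[-1]) {
    if (!is.numeric(df[[v]])) df[[v]] <- factor(df[[v]])
  }
  mm <- stats::model.matrix(formula, df)
  if (nrow(df) < qr(mm)$rank + 1) {
    abort("not enough observations for the requested model")
  }
  fit <- stats::lm(formula, data = df)
  an <- suppressWarnings(stats::anova(fit))
  res_row <- rownames(an) == "Residuals"
  terms_tbl <- tibble(
    term = trimws(rownames(an)[!res_row]),
    df = an$Df[!res_row],
    sumsq = an$`Sum Sq`[!res_row],
    meansq = an$`Mean Sq`[!res_row],
    statistic = an$`F value`[!res_row],
    p.value = an$`Pr(>F)`[!res_row]
  )
  residual_df <- an$Df[res_row]
  residual_ss <- an$`Sum Sq`[res_row]
  degenerate <- FALSE
  tol <- 1e-12 * max(1, sum(an$`Sum Sq`, na.rm = TRUE))
  if (residual_df == 0 || residual_ss <= tol) {
    # no residual variation: F ratios are undefined rather than infinite
    if (residual_df == 0 || all(terms_tbl$sumsq <= tol)) {
      terms_tbl$statistic <- NA_real_
      terms_tbl$p.value <- NA_real_
      degenerate <- TRUE
      warn("zero residual variation: F statistics undefined, set to NA")
    }
  }
  structure(
    list(
      terms = terms_tbl,
      residual_df = residual_df,
      residual_ss = residual_ss,
      coefficients = stats::coef(fit),
      nobs = nrow(df),
      formula = formula,
      degenerate = degenerate
    ),
    class = "te_lm"
  )
}

#' @export
print.te_lm <- function(x, ...) {
  cat("Sequential ANOVA fit:", deparse(x$formula), "\n")
  print(x$terms)
  cat("Residuals: df =", x$residual_df, ", SS =", format(x$residual_ss), "\n")
  invisible(x)
}

#' Tidy a sequential ANOVA fit
#' @param x A `te_lm` object.
#' @param ... Unused.
#' @return The per-term tibble, with the residual row appended.
#' @export
tidy.te_lm <- function(x, ...) {
  bind_rows(
    x$terms,
    tibble(term = "Residuals", df = x$residual_df, sumsq = x$residual_ss,
           meansq = x$residual_ss / max(x$residual_df, 1),
           statistic = NA_real_, p.value = NA_real_)
  )
}

#' One-row model summary of a sequential ANOVA fit
#' @param x A `te_lm` object.
#' @param ... Unused.
#' @return A one-row tibble with total/residual SS, R squared, df and n.
#' @export
glance.te_lm <- function(x, ...) {
  total_ss <- sum(x$terms$sumsq) + x$residual_ss
  tibble(
    r.squared = if (total_ss > 0) 1 - x$residual_ss / total_ss else NA_real_,
    df.residual = x$residual_df,
    residual_ss = x$residual_ss,
    total_ss = total_ss,
    nobs = x$nobs
  )
}

# Extract the p-value of one named term from a te_lm fit (NA if degenerate).
term_p_value <- function(fit, term) {
  i <- match(term, fit$terms$term)
  if (is.na(i)) return(NA_real_)
  fit$terms$p.value[i]
}
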