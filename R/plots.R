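# ggplot2 displays for the main result types.

#' Fold-change overview of a classification
#'
#' Ranked per-family log2 fold changes in genomic insertions (selected over
#' control), coloured by the classification label. Families above zero are
#' more abundant in the selected populations.
#'
#' @param classification A `te_classification` tibble (optionally with a
#'   `study` column, which facets the plot).
#' @return A ggplot object.
#' @export
plot_fold_change <- function(classification) {
  d <- as_tibble(classification) %>%
    filter(!is.na(.data$log2fc)) %>%
    arrange(.data$log2fc) %>%
    mutate(rank = row_number())
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$log2fc,
                                       colour = .data$label)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(values = c("S>C" = "#c0392b",
                                            "C>S" = "#2980b9",
                                            "NS" = "grey70")) +
    ggplot2::labs(x = "TE family (ranked)",
                  y = expression(log[2] ~ "FC insertions (S / C)"),
                  colour = NULL) +
    ggplot2::theme_minimal()
  if ("study" %in% names(d)) {
    p <- p + ggplot2::facet_wrap(~study, scales = "free_x")
  }
  p
}

#' @export
autoplot.te_classification <- function(object, ...) plot_fold_change(object)

#' Genome-wide site differentiation plot
#'
#' Manhattan-style display of per-site regime differentiation:
#' `-log10(p)` along the genome with alternating chromosome shading and the
#' Bonferroni cut-off; significant sites are coloured by the regime with
#' the higher frequency.
#'
#' @param site_tests A `te_site_tests` tibble from
#'   [site_differentiation_test()].
#' @return A ggplot object.
#' @export
plot_site_differentiation <- function(site_tests) {
  thr <- attr(site_tests, "threshold")
  d <- as_tibble(site_tests) %>%
    filter(!is.na(.data$p_regime)) %>%
    arrange(.data$chrom, .data$pos) %>%
    mutate(
      idx = row_number(),
      shade = factor(as.integer(factor(.data$chrom)) %% 2),
      colour = case_when(.data$direction == "S" ~ "S higher",
                         .data$direction == "C" ~ "C higher",
                         TRUE ~ paste0("chrom", .data$shade))
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$idx,
                                  y = -log10(.data$p_regime),
                                  colour = .data$colour)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(thr), colour = "orange") +
    ggplot2::scale_colour_manual(values = c(
      "S higher" = "#c0392b", "C higher" = "#2980b9",
      "chrom0" = "grey30", "chrom1" = "grey65"
    )) +
    ggplot2::labs(x = "TE insertion (genome order)",
                  y = expression(-log[10] ~ italic(P)), colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.te_site_tests <- function(object, ...) {
  plot_site_differentiation(object)
}

#' Drift null distribution with the observed statistic
#'
#' Histogram of the simulated S>C statistic under pure drift with the
#' observed value marked; the empirical neutrality p value is the mass at
#' or beyond the line.
#'
#' @param result A `te_drift_result` from [neutrality_pvalue()].
#' @return A ggplot object.
#' @export
plot_drift_null <- function(result) {
  d <- tibble(statistic = result$sim_statistics) %>%
    filter(!is.na(.data$statistic))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$statistic)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = result$observed_statistic,
                        colour = "#c0392b", linewidth = 1) +
    ggplot2::labs(
      x = paste0("simulated S>C ", result$statistic, " under drift"),
      y = "simulations",
      title = paste0("empirical p = ", signif(result$p.value, 3))
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.te_drift_result <- function(object, ...) plot_drift_null(object)
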