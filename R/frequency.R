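# Insertion-frequency analytics: family mean segregating frequencies, their
# relation to genomic abundance, per-site and per-family regime
# differentiation tests on arcsine-square-root transformed frequencies, and
# gene-proximity annotation of candidate sites.

#' Mean segregating frequency per TE family and population
#'
#' Averages the population frequency over all detected insertion sites of a
#' family -- the classical proxy for the family's evolutionary age and
#' recent transposition activity (young, active families segregate at low
#' frequencies). Sites with missing (`NA`) frequency in a population are
#' ignored for that population; a family with no observed site in a
#' population is absent from the result for that population.
#'
#' @param sites Long insertion tibble (`chrom`, `pos`, `family`, `sample`,
#'   `freq`).
#' @return Tibble (`family`, `sample`, `mean_freq`, `n_sites`).
#' @export
family_mean_frequency <- function(sites) {
  if (nrow(sites) == 0) abort("no insertion sites")
  sites %>%
    filter(!is.na(.data$freq)) %>%
    group_by(.data$family, .data$sample) %>%
    summarise(mean_freq = mean(.data$freq), n_sites = dplyr::n(),
              .groups = "drop")
}

#' Compare reference frequencies of C>S versus S>C TE families
#'
#' Welch t test of a reference mean frequency (e.g. from a deeply sequenced
#' natural population) between the families classified `C>S` and `S>C`.
#' With `top_n` set, each group is first restricted to its `top_n` families
#' by absolute log2 fold change (ties broken by family name, so the
#' selection is deterministic); a `top_n` larger than the group uses the
#' whole group.
#'
#' @param freqs Tibble (`family`, `freq`) of reference frequencies.
#' @param classification A `te_classification` tibble with `log2fc`.
#' @param top_n Optional group size restriction.
#' @return One-row tibble (Welch t); `estimate` is mean(C>S) - mean(S>C).
#' @export
frequency_group_comparison <- function(freqs, classification, top_n = NULL) {
  d <- classification %>%
    filter(.data$label %in% c("S>C", "C>S")) %>%
    left_join(freqs, by = "family") %>%
    filter(!is.na(.data$freq))
  if (!is.null(top_n)) {
    d <- d %>%
      group_by(.data$label) %>%
      arrange(dplyr::desc(abs(.data$log2fc)), .data$family,
              .by_group = TRUE) %>%
      dplyr::slice_head(n = top_n) %>%
      ungroup()
  }
  a <- d$freq[d$label == "C>S"]; b <- d$freq[d$label == "S>C"]
  if (length(a) < 2 || length(b) < 2) {
    return(test_row("Welch t-test", note = "group of size < 2"))
  }
  welch_t_test(a, b)
}

#' Correlation between genomic abundance and mean family frequency
#'
#' Spearman rank correlation across families between copy number and mean
#' segregating frequency -- expected to be negative (abundant families are
#' typically old and rare-per-site young families many-copied). Either the
#' per-family means over populations are correlated once (`by = "mean"`) or
#' one correlation per population is returned (`by = "population"`).
#'
#' @param abundance Abundance tibble (`family`, `sample`, `insertions`).
#' @param freqs Family frequency tibble from [family_mean_frequency()].
#' @param by `"mean"` (default) or `"population"`.
#' @return One-row tibble, or one row per population.
#' @export
abundance_frequency_correlation <- function(abundance, freqs,
                                            by = c("mean", "population")) {
  by <- match.arg(by)
  if (by == "mean") {
    a <- abundance %>%
      group_by(.data$family) %>%
      summarise(insertions = mean(.data$insertions), .groups = "drop")
    f <- freqs %>%
      group_by(.data$family) %>%
      summarise(mean_freq = mean(.data$mean_freq), .groups = "drop")
    d <- dplyr::inner_join(a, f, by = "family")
    if (nrow(d) < 3) abort("need at least 3 shared families")
    return(rank_correlation(d$insertions, d$mean_freq, "spearman"))
  }
  d <- dplyr::inner_join(abundance, freqs, by = c("family", "sample"))
  d %>%
    group_by(.data$sample) %>%
    dplyr::group_map(function(g, key) {
      if (nrow(g) < 3) abort("need at least 3 shared families")
      mutate(rank_correlation(g$insertions, g$mean_freq, "spearman"),
             sample = key$sample)
    }) %>%
    bind_rows()
}

site_test_formula <- function(design) {
  if (has_diet_structure(design)) {
    freq_t ~ diet + regime + diet:regime
  } else {
    freq_t ~ regime
  }
}

#' Per-site regime differentiation of insertion frequencies
#'
#' For every genomic insertion site, fits a sequential ANOVA on the
#' arcsine-square-root transformed population frequencies (Regime only, or
#' Diet + Regime + Diet x Regime for diet-structured designs) and flags
#' sites whose regime term passes the Bonferroni threshold
#' `alpha / n_tested`. Populations with missing frequency are dropped per
#' site; sites with fewer than two populations per regime are skipped and
#' counted.
#'
#' @param sites Long insertion tibble.
#' @param design Study design tibble.
#' @param alpha Family-wise error rate (default 0.05).
#' @return A `te_site_tests` tibble: site key, `p_regime`, `significant`,
#'   `direction` (`"S"`/`"C"`, only for significant sites). Attributes
#'   `n_tested`, `n_skipped` and `threshold` record the correction.
#' @export
site_differentiation_test <- function(sites, design, alpha = 0.05) {
  design <- validate_design(design)
  meta <- design[, c("sample", "regime", "diet")]
  form <- site_test_formula(design)
  per_site <- sites %>%
    filter(!is.na(.data$freq)) %>%
    left_join(meta, by = "sample") %>%
    group_by(.data$chrom, .data$pos, .data$family)
  res <- per_site %>%
    dplyr::group_map(function(d, key) {
      enough <- sum(d$regime == "S") >= 2 && sum(d$regime == "C") >= 2
      if (!enough) {
        return(mutate(key, p_regime = NA_real_, mean_s = NA_real_,
                      mean_c = NA_real_, tested = FALSE))
      }
      d$freq_t <- arcsine_sqrt(d$freq)
      # invariant sites (e.g. fixed everywhere) legitimately yield NA F
      fit <- suppressWarnings(fit_fixed_lm(d, form))
      mutate(key,
             p_regime = term_p_value(fit, "regime"),
             mean_s = mean(d$freq[d$regime == "S"]),
             mean_c = mean(d$freq[d$regime == "C"]),
             tested = TRUE)
    }) %>%
    bind_rows()
  n_skipped <- sum(!res$tested)
  if (n_skipped > 0) {
    inform(paste0("skipped ", n_skipped,
                  " site(s) with < 2 populations per regime"))
  }
  n_tested <- sum(res$tested & !is.na(res$p_regime))
  threshold <- bonferroni_threshold(alpha, max(n_tested, 1))
  out <- res %>%
    mutate(
      significant = .data$tested & !is.na(.data$p_regime) &
        .data$p_regime < threshold,
      direction = case_when(
        .data$significant & .data$mean_s > .data$mean_c ~ "S",
        .data$significant & .data$mean_s < .data$mean_c ~ "C",
        TRUE ~ NA_character_
      )
    ) %>%
    select("chrom", "pos", "family", "p_regime", "significant", "direction")
  structure(out, class = c("te_site_tests", class(out)),
            n_tested = n_tested, n_skipped = n_skipped,
            threshold = threshold, alpha = alpha)
}

family_test_formula <- function(design) {
  if (has_diet_structure(design)) {
    freq_t ~ diet + regime + diet:regime
  } else {
    freq_t ~ regime + regime:population
  }
}

#' Per-family regime differentiation of insertion frequencies
#'
#' For every family with at least `min_sites` detected sites, pools the
#' arcsine-square-root transformed site-by-population frequencies as
#' observations of one sequential ANOVA (Regime and populations nested in
#' regime, or the diet model) and adjusts the regime p values across
#' families with Benjamini-Hochberg. Optionally intersects the FDR
#' discoveries with an abundance classification to report the families
#' significant for both abundance and frequency.
#'
#' @param sites Long insertion tibble.
#' @param design Study design tibble.
#' @param fdr FDR threshold (default 0.05).
#' @param min_sites Minimum number of sites per family (default 2).
#' @param classification Optional `te_classification` to intersect with.
#' @return Tibble with columns `family`, `n_sites`, `p_regime`,
#'   `p_adjusted`, `significant` and, when a classification is supplied,
#'   `joint_significant`.
#' @export
family_frequency_regime_test <- function(sites, design, fdr = 0.05,
                                         min_sites = 2,
                                         classification = NULL) {
  design <- validate_design(design)
  meta <- design[, c("sample", "regime", "replicate", "diet")]
  form <- family_test_formula(design)
  res <- sites %>%
    filter(!is.na(.data$freq)) %>%
    left_join(meta, by = "sample") %>%
    rename(population = "replicate") %>%
    group_by(.data$family) %>%
    dplyr::group_map(function(d, key) {
      n_sites <- dplyr::n_distinct(paste(d$chrom, d$pos))
      if (n_sites < min_sites) {
        return(tibble(family = key$family, n_sites = n_sites,
                      p_regime = NA_real_))
      }
      d$freq_t <- arcsine_sqrt(d$freq)
      fit <- tryCatch(suppressWarnings(fit_fixed_lm(d, form)),
                      error = function(e) NULL)
      tibble(family = key$family, n_sites = n_sites,
             p_regime = if (is.null(fit)) NA_real_ else
               term_p_value(fit, "regime"))
    }) %>%
    bind_rows() %>%
    mutate(p_adjusted = bh_adjust(.data$p_regime),
           significant = !is.na(.data$p_adjusted) & .data$p_adjusted < fdr)
  if (!is.null(classification)) {
    abundance_sig <- classification$family[classification$label != "NS"]
    res <- res %>%
      mutate(joint_significant = .data$significant &
               .data$family %in% abundance_sig)
  }
  res
}

#' Annotate insertion sites with gene proximity
#'
#' Classifies every distinct site as `inside` a gene (start <= pos <= end),
#' `upstream` or `downstream` of the nearest gene within `window` bp
#' (inclusive at exactly `window`), or `intergenic`. Upstream/downstream is
#' resolved by gene strand: a site genomically before the start of a
#' plus-strand gene is upstream of it, before a minus-strand gene
#' downstream, and so on. When several genes qualify the nearest wins, with
#' ties broken by the lexicographically smallest gene id. The window is
#' measured from the annotated gene start/end.
#'
#' @param sites Insertion tibble (long or already distinct sites).
#' @param genes Gene interval tibble (see [read_gene_intervals()]).
#' @param window Proximity window in bp (default 1000).
#' @return Distinct-site tibble (`chrom`, `pos`, `family`, `relation`,
#'   `gene_id`, `distance`).
#' @export
annotate_sites <- function(sites, genes, window = 1000) {
  genes <- validate_gene_intervals(genes)
  keys <- sites %>% distinct(.data$chrom, .data$pos, .data$family)
  annotate_chrom <- function(d) {
    g <- genes %>% filter(.data$chromosome == d$chrom[1])
    if (nrow(g) == 0) {
      return(mutate(d, relation = "intergenic", gene_id = NA_character_,
                    distance = NA_real_))
    }
    # distance from site to each gene: 0 inside, else bp to nearest edge
    res <- purrr::pmap_dfr(d, function(chrom, pos, family) {
      before <- pos < g$start
      after <- pos > g$end
      dist <- ifelse(before, g$start - pos, ifelse(after, pos - g$end, 0))
      ord <- order(dist, g$gene_id)
      best <- ord[1]
      bd <- dist[best]
      relation <- if (bd == 0) {
        "inside"
      } else if (bd <= window) {
        if (pos < g$start[best]) {
          if (g$strand[best] == "+") "upstream" else "downstream"
        } else {
          if (g$strand[best] == "+") "downstream" else "upstream"
        }
      } else {
        "intergenic"
      }
      tibble(chrom = chrom, pos = pos, family = family, relation = relation,
             gene_id = if (relation == "intergenic") NA_character_ else
               g$gene_id[best],
             distance = if (relation == "intergenic") NA_real_ else bd)
    })
    res
  }
  keys %>%
    group_by(.data$chrom) %>%
    dplyr::group_map(~ annotate_chrom(mutate(.x, chrom = .y$chrom))) %>%
    bind_rows() %>%
    arrange(.data$chrom, .data$pos, .data$family)
}
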