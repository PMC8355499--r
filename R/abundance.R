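# Family-level abundance analyses: the coverage filter, per-population
# abundance estimates, the three regime classification approaches, fold
# change statistics, genomic content models, subclass enrichment, and the
# copy-number correction of expression counts.

#' Filter TE families by coverage support
#'
#' A family is retained when, averaging the normalised per-position values
#' across all populations of the study, at least 80% of its consensus
#' positions have a study-average of at least `min_insertions` (default
#' 0.5). Exactly 80% counts as retained. Families with very low or patchy
#' coverage -- mostly absent or near-zero-copy families -- are excluded from
#' all downstream analyses.
#'
#' @param coverage Coverage tibble (`family`, `sample`, `pos`, `insertions`).
#' @param min_insertions Study-average insertion threshold per position.
#' @param min_fraction Minimum fraction of positions meeting the threshold.
#' @return Character vector of retained family names.
#' @export
filter_families <- function(coverage, min_insertions = 0.5,
                            min_fraction = 0.8) {
  per_pos <- coverage %>%
    group_by(.data$family, .data$pos) %>%
    summarise(avg = mean(.data$insertions), .groups = "drop_last") %>%
    summarise(frac_ok = mean(.data$avg >= min_insertions),
              n_pos = dplyr::n(), .groups = "drop")
  empty <- per_pos$family[per_pos$n_pos == 0]
  if (length(empty) > 0) {
    warn(paste0("excluding ", length(empty), " family/families with no positions"))
  }
  sort(per_pos$family[per_pos$frac_ok >= min_fraction & per_pos$n_pos > 0])
}

#' Estimate per-population TE family abundance
#'
#' Averages the normalised per-position values over all consensus positions,
#' giving one insertion estimate per family and population (insertions per
#' haploid genome).
#'
#' @param coverage Coverage tibble.
#' @param retained Families to keep (default: all in the table).
#' @return Abundance tibble (`family`, `sample`, `insertions`).
#' @export
estimate_abundance <- function(coverage, retained = NULL) {
  if (!is.null(retained)) {
    coverage <- coverage %>% filter(.data$family %in% retained)
  }
  coverage %>%
    group_by(.data$family, .data$sample) %>%
    summarise(insertions = mean(.data$insertions), .groups = "drop")
}

#' Per-family log2 fold change and insertion difference between regimes
#'
#' `log2fc = log2(mean_S / mean_C)` and `delta_insertion = mean_S - mean_C`,
#' where the regime means average the per-population abundance estimates. No
#' pseudo-count is used: the retention filter makes zero regime means
#' practically impossible, and a non-positive mean yields an `NA` fold
#' change while the difference is still returned.
#'
#' @param abundance Abundance tibble (`family`, `sample`, `insertions`).
#' @param design Study design tibble.
#' @return Tibble with `family`, `mean_s`, `mean_c`, `log2fc`,
#'   `delta_insertion`.
#' @export
fold_changes <- function(abundance, design) {
  joined <- abundance %>%
    left_join(design[, c("sample", "regime")], by = "sample")
  if (any(is.na(joined$regime))) abort("abundance contains undeclared samples")
  joined %>%
    group_by(.data$family) %>%
    summarise(
      mean_s = mean(.data$insertions[.data$regime == "S"]),
      mean_c = mean(.data$insertions[.data$regime == "C"]),
      .groups = "drop"
    ) %>%
    mutate(
      log2fc = ifelse(.data$mean_s > 0 & .data$mean_c > 0,
                      log2(.data$mean_s / .data$mean_c), NA_real_),
      delta_insertion = .data$mean_s - .data$mean_c
    )
}

approach1_formula <- function(design) {
  if (has_diet_structure(design)) {
    insertions ~ regime + diet + regime:diet
  } else {
    insertions ~ regime + regime:population
  }
}

#' Classify TE families per study (approach #1)
#'
#' The least conservative classification: for every retained family, fit a
#' sequential ANOVA on the per-position normalised values -- regime plus
#' replicate populations nested within regime, or regime, diet and their
#' interaction for diet-structured designs -- and call a family `S>C` or
#' `C>S` when (a) its regime term passes Bonferroni correction across the
#' retained families at `alpha`, and (b) the regime abundance means differ
#' by more than `delta_min` insertions (filtering out significant but tiny
#' differences). Everything else is `NS`.
#'
#' @param coverage Coverage tibble of one study.
#' @param design The study's design tibble.
#' @param alpha Family-wise error rate for the Bonferroni criterion
#'   (default 0.01).
#' @param delta_min Minimum absolute regime difference in insertions
#'   (default 0.3).
#' @param retained Optional pre-computed retained family list; defaults to
#'   [filter_families()] on `coverage`.
#' @return A `te_classification` tibble: `family`, `label`, `p_raw`,
#'   `p_adjusted`, `log2fc`, `delta_insertion`.
#' @export
classify_approach1 <- function(coverage, design, alpha = 0.01,
                               delta_min = 0.3, retained = NULL) {
  design <- validate_design(design)
  if (is.null(retained)) retained <- filter_families(coverage)
  if (length(retained) == 0) abort("no families retained")
  fc <- fold_changes(estimate_abundance(coverage, retained), design)
  form <- approach1_formula(design)
  meta <- design[, c("sample", "regime", "replicate", "diet")]
  p_raw <- purrr::map_dbl(retained, function(fam) {
    dat <- coverage %>%
      filter(.data$family == fam) %>%
      left_join(meta, by = "sample") %>%
      rename(population = "replicate")
    fit <- tryCatch(fit_fixed_lm(dat, form),
                    error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    term_p_value(fit, "regime")
  })
  n_tests <- sum(!is.na(p_raw))
  threshold <- bonferroni_threshold(alpha, max(n_tests, 1))
  res <- tibble(family = retained, p_raw = p_raw) %>%
    mutate(p_adjusted = pmin(1, .data$p_raw * n_tests)) %>%
    left_join(fc, by = "family") %>%
    mutate(
      significant = !is.na(.data$p_raw) & .data$p_raw < threshold &
        abs(.data$delta_insertion) > delta_min,
      label = case_when(
        .data$significant & .data$delta_insertion > 0 ~ "S>C",
        .data$significant & .data$delta_insertion < 0 ~ "C>S",
        TRUE ~ "NS"
      )
    ) %>%
    select("family", "label", "p_raw", "p_adjusted", "log2fc",
           "delta_insertion")
  new_classification(res, approach = 1L, alpha = alpha,
                     delta_min = delta_min, n_tests = n_tests)
}

new_classification <- function(df, ...) {
  structure(df, class = c("te_classification", class(df)), params = list(...))
}

#' Classify TE families jointly across studies (approach #2)
#'
#' Works on the arcsine-square-root transformed proportion of a family's
#' copy number relative to the total genomic TE content of each population,
#' and fits, per family, a sequential ANOVA with Study, Regime and the
#' Study x Regime interaction across all studies together. Only families
#' retained in every study enter. Regime p values are Benjamini-Hochberg
#' adjusted across families and called at `fdr`; direction comes from the
#' pooled regime means of the transformed proportion.
#'
#' @param abundance Combined abundance tibble with a `study` column
#'   (`study`, `family`, `sample`, `insertions`), containing each study's
#'   retained families only.
#' @param design Combined design tibble covering all studies.
#' @param fdr False discovery rate threshold (default 0.05).
#' @return A `te_classification` tibble with `family`, `label`, `p_raw`,
#'   `p_adjusted`, `log2fc` (pooled), `delta_insertion` (pooled).
#' @export
classify_approach2 <- function(abundance, design, fdr = 0.05) {
  design <- validate_design(design)
  studies <- unique(abundance$study)
  if (length(studies) < 2) abort("approach #2 needs at least two studies")
  common <- abundance %>%
    distinct(.data$study, .data$family) %>%
    dplyr::count(.data$family) %>%
    filter(.data$n == length(studies)) %>%
    pull(.data$family)
  if (length(common) == 0) abort("no family retained in every study")
  props <- abundance %>%
    group_by(.data$study, .data$sample) %>%
    mutate(total = sum(.data$insertions)) %>%
    ungroup() %>%
    filter(.data$family %in% common) %>%
    mutate(prop_t = arcsine_sqrt(.data$insertions / .data$total)) %>%
    left_join(design[, c("sample", "regime")], by = "sample")
  fits <- props %>%
    group_by(.data$family) %>%
    dplyr::group_map(function(d, key) {
      fit <- fit_fixed_lm(d, prop_t ~ study + regime + study:regime)
      tibble(
        family = key$family,
        p_raw = term_p_value(fit, "regime"),
        mean_s_t = mean(d$prop_t[d$regime == "S"]),
        mean_c_t = mean(d$prop_t[d$regime == "C"])
      )
    }) %>%
    bind_rows()
  pooled_fc <- fold_changes(
    abundance %>% filter(.data$family %in% common), design
  )
  res <- fits %>%
    mutate(
      p_adjusted = bh_adjust(.data$p_raw),
      label = case_when(
        !is.na(.data$p_adjusted) & .data$p_adjusted < fdr &
          .data$mean_s_t > .data$mean_c_t ~ "S>C",
        !is.na(.data$p_adjusted) & .data$p_adjusted < fdr &
          .data$mean_s_t < .data$mean_c_t ~ "C>S",
        TRUE ~ "NS"
      )
    ) %>%
    left_join(pooled_fc[, c("family", "log2fc", "delta_insertion")],
              by = "family") %>%
    select("family", "label", "p_raw", "p_adjusted", "log2fc",
           "delta_insertion")
  new_classification(res, approach = 2L, fdr = fdr,
                     n_common = length(common))
}

#' Classify TE families by replicate consistency (approach #3)
#'
#' The most conservative rule: a family is `S>C` only when every selected
#' population's abundance exceeds every control population's (strict
#' all-pairwise dominance, `min(S) > max(C)`), `C>S` for the mirror image,
#' otherwise `NS`. For diet-structured designs the rule is applied within
#' each diet and one row per (family, diet) is returned. No test statistic
#' is involved, so the labels are invariant to any common monotone
#' rescaling.
#'
#' @param abundance Abundance tibble of one study.
#' @param design The study's design tibble.
#' @return A `te_classification` tibble: `family`, (`diet`,) `label`,
#'   `log2fc`, `delta_insertion`.
#' @export
classify_approach3 <- function(abundance, design) {
  design <- validate_design(design)
  joined <- abundance %>%
    left_join(design[, c("sample", "regime", "diet")], by = "sample")
  if (any(is.na(joined$regime))) abort("abundance contains undeclared samples")
  per_diet <- has_diet_structure(design)
  grouping <- if (per_diet) c("family", "diet") else "family"
  res <- joined %>%
    group_by(dplyr::across(dplyr::all_of(grouping))) %>%
    summarise(
      min_s = min(.data$insertions[.data$regime == "S"]),
      max_s = max(.data$insertions[.data$regime == "S"]),
      min_c = min(.data$insertions[.data$regime == "C"]),
      max_c = max(.data$insertions[.data$regime == "C"]),
      mean_s = mean(.data$insertions[.data$regime == "S"]),
      mean_c = mean(.data$insertions[.data$regime == "C"]),
      .groups = "drop"
    ) %>%
    mutate(
      label = case_when(
        .data$min_s > .data$max_c ~ "S>C",
        .data$max_s < .data$min_c ~ "C>S",
        TRUE ~ "NS"
      ),
      log2fc = ifelse(.data$mean_s > 0 & .data$mean_c > 0,
                      log2(.data$mean_s / .data$mean_c), NA_real_),
      delta_insertion = .data$mean_s - .data$mean_c
    ) %>%
    select(dplyr::all_of(grouping), "label", "log2fc", "delta_insertion")
  new_classification(res, approach = 3L, per_diet = per_diet)
}

#' Compare magnitudes of abundance change between groups and studies
#'
#' Three comparisons on the classified (non-`NS`) families: per study, a
#' Welch t test of `|log2fc|` between the `C>S` and `S>C` groups; a one-way
#' ANOVA of `|log2fc|` with Study as single term followed by pairwise Welch
#' t tests with Holm adjustment; and per study, a Welch t test of the
#' absolute insertion difference (`|delta_insertion|`) between the two
#' groups.
#'
#' @param classifications Tibble binding per-study `te_classification`
#'   results with a `study` column.
#' @return A list with `group_fc_tests` (per-study tibble),
#'   `study_anova` (`te_lm`), `study_pairwise` (tibble) and
#'   `group_delta_tests` (per-study tibble).
#' @export
magnitude_comparisons <- function(classifications) {
  sig <- classifications %>%
    filter(.data$label %in% c("S>C", "C>S"), !is.na(.data$log2fc))
  if (nrow(sig) == 0) abort("no classified families to compare")
  one_study <- function(d, value) {
    a <- abs(value[d$label == "C>S"])
    b <- abs(value[d$label == "S>C"])
    if (length(a) < 2 || length(b) < 2) {
      return(test_row("Welch t-test", note = "group of size < 2"))
    }
    welch_t_test(a, b)
  }
  group_fc <- sig %>%
    group_by(.data$study) %>%
    dplyr::group_map(~ mutate(one_study(.x, .x$log2fc), study = .y$study)) %>%
    bind_rows()
  group_delta <- sig %>%
    group_by(.data$study) %>%
    dplyr::group_map(
      ~ mutate(one_study(.x, .x$delta_insertion), study = .y$study)
    ) %>%
    bind_rows()
  anova_df <- sig %>% mutate(abs_fc = abs(.data$log2fc))
  study_anova <- fit_fixed_lm(anova_df, abs_fc ~ study)
  study_pairwise <- pairwise_group_comparison(anova_df$abs_fc,
                                              anova_df$study)
  list(group_fc_tests = group_fc, study_anova = study_anova,
       study_pairwise = study_pairwise, group_delta_tests = group_delta)
}

#' Total and subclass genomic TE content models
#'
#' Sums the per-population insertion estimates over all retained families
#' (and within each subclass) and fits sequential ANOVAs with Study, Regime
#' and the Study x Regime interaction, plus within-study pairwise regime
#' contrasts (Welch t tests).
#'
#' @param abundance Combined abundance tibble with `study` column.
#' @param hierarchy Hierarchy tibble mapping families to subclasses.
#' @param design Combined design tibble.
#' @return A list with `totals` (per-population content tibble), `models`
#'   (named list of `te_lm`: `total`, one per subclass present) and
#'   `within_study` (per study and scope Welch t of content between
#'   regimes).
#' @export
content_tests <- function(abundance, hierarchy, design) {
  design <- validate_design(design)
  joined <- abundance %>%
    left_join(hierarchy[, c("family", "subclass")], by = "family") %>%
    left_join(design[, c("sample", "regime")], by = "sample")
  totals <- bind_rows(
    joined %>%
      group_by(.data$study, .data$sample, .data$regime) %>%
      summarise(content = sum(.data$insertions), .groups = "drop") %>%
      mutate(scope = "total"),
    joined %>%
      filter(!is.na(.data$subclass)) %>%
      group_by(.data$study, .data$sample, .data$regime, .data$subclass) %>%
      summarise(content = sum(.data$insertions), .groups = "drop") %>%
      rename(scope = "subclass")
  )
  scopes <- unique(totals$scope)
  models <- purrr::map(setNames(scopes, scopes), function(sc) {
    d <- totals %>% filter(.data$scope == sc)
    if (length(unique(d$study)) > 1) {
      fit_fixed_lm(d, content ~ study + regime + study:regime)
    } else {
      fit_fixed_lm(d, content ~ regime)
    }
  })
  within_study <- totals %>%
    group_by(.data$study, .data$scope) %>%
    dplyr::group_map(function(d, key) {
      s <- d$content[d$regime == "S"]; c0 <- d$content[d$regime == "C"]
      out <- if (length(s) >= 2 && length(c0) >= 2) welch_t_test(s, c0) else
        test_row("Welch t-test", note = "regime with < 2 populations")
      mutate(out, study = key$study, scope = key$scope)
    }) %>%
    bind_rows()
  list(totals = totals, models = models, within_study = within_study)
}

#' Subclass and class enrichment of classified TE groups
#'
#' For each classified group (`S>C`, `C>S`) and each type contrast (TIR
#' subclass vs the rest; DNA vs RNA class), a two-sided Fisher exact test of
#' group membership against the background of all classified families.
#'
#' @param classification A `te_classification` tibble (one study).
#' @param hierarchy Hierarchy tibble.
#' @return Tibble with one row per (group, type) and the Fisher test
#'   results.
#' @export
subclass_enrichment <- function(classification, hierarchy) {
  d <- classification %>%
    left_join(hierarchy[, c("family", "subclass", "te_class")], by = "family")
  contrasts <- list(
    TIR = d$subclass == "TIR",
    DNA_class = d$te_class == "DNA"
  )
  out <- purrr::map_dfr(c("S>C", "C>S"), function(grp) {
    in_grp <- d$label == grp
    if (sum(in_grp) == 0) return(tibble())
    purrr::map_dfr(names(contrasts), function(ty) {
      is_type <- contrasts[[ty]]
      tab <- matrix(c(
        sum(in_grp & is_type), sum(in_grp & !is_type),
        sum(!in_grp & is_type), sum(!in_grp & !is_type)
      ), nrow = 2, byrow = TRUE)
      mutate(fisher_exact_2x2(tab), group = grp, type = ty,
             n_group = sum(in_grp), n_type_in_group = sum(in_grp & is_type))
    })
  })
  out
}

#' Correct expression counts by genomic copy number
#'
#' Divides per-family read counts by the number of genomic insertions
#' observed in the matching population, to examine average expression per
#' insertion. Families absent from the abundance table (e.g. filtered out
#' of the genomic analysis) are assumed to have a single copy, as are
#' zero-copy entries (with a warning).
#'
#' @param counts Tibble (`family`, `sample`, `count`).
#' @param abundance Abundance tibble (`family`, `sample`, `insertions`).
#' @return `counts` with columns `copies` and `corrected`.
#' @export
correct_counts_by_copies <- function(counts, abundance) {
  stopifnot(all(counts$count >= 0))
  out <- counts %>%
    left_join(abundance %>% rename(copies = "insertions"),
              by = c("family", "sample"))
  zero <- !is.na(out$copies) & out$copies == 0
  if (any(zero)) {
    warn(paste0(sum(zero), " zero-copy entries treated as single copy"))
    out$copies[zero] <- 1
  }
  out$copies[is.na(out$copies)] <- 1
  out %>% mutate(corrected = .data$count / .data$copies)
}
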