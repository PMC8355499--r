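# Cross-study sharing analyses: exact overlap tests of classified family
# sets, pairwise fold-change correlations, and the TE-versus-gene
# expression-category comparison.

#' Exact overlap tests of classified families across studies
#'
#' For every subset of two or more studies and each direction group (`S>C`,
#' `C>S`), computes the intersection of the studies' significant family sets
#' and its probability under independent uniform sampling from the common
#' background ([multiset_intersection_test()]). The background is the set of
#' families retained in every study -- families unobservable in a study
#' cannot be called in it. A subset containing a study with an empty group
#' is reported with `k = 0, p = 1`.
#'
#' @param classifications Tibble binding per-study classifications with a
#'   `study` column (`study`, `family`, `label`).
#' @param background Character vector of common retained families; default
#'   is the intersection of each study's family lists.
#' @param sig_level Significance flag threshold on the overlap p value
#'   (default 0.05, unadjusted).
#' @return Tibble with one row per (study subset, group): `studies`,
#'   `n_studies`, `group`, `intersection`, `set_sizes`, `background_n`,
#'   `p.value`, `significant`.
#' @export
cross_study_overlaps <- function(classifications, background = NULL,
                                 sig_level = 0.05) {
  studies <- sort(unique(classifications$study))
  if (length(studies) < 2) abort("need at least two studies")
  if (is.null(background)) {
    background <- purrr::reduce(
      purrr::map(studies,
                 ~ unique(classifications$family[classifications$study == .x])),
      intersect
    )
  }
  n_bg <- length(background)
  if (n_bg == 0) abort("empty background")
  sets <- purrr::map(setNames(studies, studies), function(st) {
    d <- classifications[classifications$study == st, ]
    list(
      "S>C" = intersect(d$family[d$label == "S>C"], background),
      "C>S" = intersect(d$family[d$label == "C>S"], background)
    )
  })
  combos <- purrr::map(2:length(studies),
                       ~ utils::combn(studies, .x, simplify = FALSE)) %>%
    purrr::flatten()
  out <- purrr::map_dfr(combos, function(cmb) {
    purrr::map_dfr(c("S>C", "C>S"), function(grp) {
      members <- purrr::map(cmb, ~ sets[[.x]][[grp]])
      sizes <- lengths(members)
      k <- length(purrr::reduce(members, intersect))
      p <- if (any(sizes == 0)) 1 else
        multiset_intersection_test(n_bg, sizes, k)$p.value
      tibble(
        studies = paste(cmb, collapse = "+"), n_studies = length(cmb),
        group = grp, intersection = k,
        set_sizes = paste(sizes, collapse = ","), background_n = n_bg,
        p.value = p, significant = p < sig_level
      )
    })
  })
  out
}

#' Pairwise fold-change correlations between studies
#'
#' Spearman rank correlation of per-family log2 fold changes for every pair
#' of studies, over the families shared between the pair.
#'
#' @param classifications Tibble with `study`, `family`, `log2fc`.
#' @param min_shared Minimum number of shared families (default 3); pairs
#'   below it are returned with `NA`.
#' @return Tibble with one row per study pair.
#' @export
pairwise_fc_correlation <- function(classifications, min_shared = 3) {
  studies <- sort(unique(classifications$study))
  pairs <- utils::combn(studies, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    s1 <- pairs[1, i]; s2 <- pairs[2, i]
    d1 <- classifications[classifications$study == s1,
                          c("family", "log2fc")]
    d2 <- classifications[classifications$study == s2,
                          c("family", "log2fc")]
    d <- dplyr::inner_join(d1, d2, by = "family", suffix = c("_1", "_2")) %>%
      filter(!is.na(.data$log2fc_1), !is.na(.data$log2fc_2))
    if (nrow(d) < min_shared) {
      return(tibble(study1 = s1, study2 = s2, n_shared = nrow(d),
                    estimate = NA_real_, p.value = NA_real_))
    }
    ct <- rank_correlation(d$log2fc_1, d$log2fc_2, "spearman")
    tibble(study1 = s1, study2 = s2, n_shared = nrow(d),
           estimate = ct$estimate, p.value = ct$p.value)
  })
}

#' Compare expression-category proportions of TE families and genes
#'
#' Chi-square comparison of the up / down / unchanged proportions between TE
#' families and genes for one factor level (e.g. regime in females). A
#' category empty in both rows is dropped with a message.
#'
#' @param te_counts,gene_counts Named numeric vectors with entries `up`,
#'   `down`, `ns`.
#' @return One-row tibble from [chi_square_contingency()].
#' @export
te_vs_gene_proportions <- function(te_counts, gene_counts) {
  cats <- c("up", "down", "ns")
  stopifnot(all(cats %in% names(te_counts)),
            all(cats %in% names(gene_counts)))
  tab <- rbind(TE = te_counts[cats], gene = gene_counts[cats])
  empty <- colSums(tab) == 0
  if (any(empty)) {
    inform(paste0("dropping empty category column(s): ",
                  paste(cats[empty], collapse = ", ")))
    tab <- tab[, !empty, drop = FALSE]
  }
  chi_square_contingency(tab)
}
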