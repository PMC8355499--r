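# Small in-code fixtures shared across test files.

tiny_design <- function(n_control = 2, n_selected = 2, study = "Tiny",
                        diets = "none", pool_size = 50) {
  study_design(study, n_control, n_selected, diets = diets,
               pool_size = pool_size)
}

# Coverage tibble with a constant value per (family, sample).
flat_coverage <- function(values, n_positions = 5) {
  # values: tibble(family, sample, value)
  tidyr::expand_grid(values, pos = seq_len(n_positions)) %>%
    dplyr::transmute(family, sample, pos, insertions = value)
}

# Abundance tibble from named per-sample values for one family.
abundance_row <- function(family, values) {
  tibble::tibble(family = family, sample = names(values),
                 insertions = unname(values))
}

# Long insertion tibble from a wide matrix: rows = sites, cols = samples.
sites_from_matrix <- function(mat, family = "TE001", chrom = "chr1") {
  tibble::as_tibble(mat, .name_repair = "minimal") %>%
    stats::setNames(colnames(mat)) %>%
    dplyr::mutate(chrom = chrom, pos = seq_len(nrow(mat)) * 100L,
                  family = family) %>%
    tidyr::pivot_longer(dplyr::all_of(colnames(mat)), names_to = "sample",
                        values_to = "freq")
}

gene_tbl <- function(...) {
  tibble::tibble(...)
}
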