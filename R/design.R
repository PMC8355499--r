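#' Construct a study design table
#'
#' A study design describes the pool-sequenced populations of one selection
#' experiment: for every population its breeding regime (`"C"` early-breeding
#' control or `"S"` late-breeding selected), replicate identifier, larval diet
#' (`"none"` for designs without a diet treatment) and pool size (number of
#' diploid females pooled for sequencing).
#'
#' @param study Study name (character scalar).
#' @param n_control,n_selected Number of replicate populations per regime
#'   (within each diet for diet-structured designs).
#' @param diets Character vector of diet levels; `"none"` for designs without
#'   a diet treatment.
#' @param pool_size Number of individuals per sequencing pool.
#'
#' @return A tibble with columns `study`, `sample`, `regime`, `replicate`,
#'   `diet`, `pool_size`; one row per population.
#' @examples
#' study_design("Remolina2012", n_control = 3, n_selected = 3)
#' @export
study_design <- function(study, n_control, n_selected, diets = "none",
                         pool_size = 125) {
  stopifnot(n_control >= 1, n_selected >= 1, length(diets) >= 1)
  rows <- purrr::map_dfr(diets, function(d) {
    bind_rows(
      tibble(regime = "C", replicate = paste0("C", seq_len(n_control)), diet = d),
      tibble(regime = "S", replicate = paste0("S", seq_len(n_selected)), diet = d)
    )
  })
  out <- rows %>%
    mutate(
      study = study,
      pool_size = as.integer(pool_size),
      sample = ifelse(.data$diet == "none",
        paste(study, .data$replicate, sep = "_"),
        paste(study, .data$diet, .data$replicate, sep = "_")
      )
    ) %>%
    select("study", "sample", "regime", "replicate", "diet", "pool_size")
  validate_design(out)
}

#' Validate a study design table
#'
#' Checks the invariants every televolve analysis relies on: regimes are `"C"`
#' or `"S"`, at least one population per regime, unique
#' (study, regime, replicate, diet) combinations, positive pool sizes.
#'
#' @param design A design tibble as built by [study_design()].
#' @return The validated design (invisibly usable in pipes).
#' @export
validate_design <- function(design) {
  req <- c("study", "sample", "regime", "replicate", "diet", "pool_size")
  miss <- setdiff(req, names(design))
  if (length(miss) > 0) {
    abort(paste0("design is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!all(design$regime %in% c("C", "S"))) {
    abort("regime must be 'C' or 'S'")
  }
  for (st in unique(design$study)) {
    d <- design[design$study == st, ]
    if (!all(c("C", "S") %in% d$regime)) {
      abort(paste0("study '", st, "' needs at least one population per regime"))
    }
  }
  key <- paste(design$study, design$regime, design$replicate, design$diet)
  if (anyDuplicated(key) > 0) {
    abort("duplicate (study, regime, replicate, diet) combination in design")
  }
  if (anyDuplicated(design$sample) > 0) abort("sample names must be unique")
  if (any(design$pool_size <= 0)) abort("pool_size must be > 0")
  as_tibble(design)
}

#' Default multi-study designs emulating four longevity-selection experiments
#'
#' Returns population layouts and drift-relevant demographic parameters for
#' four synthetic studies patterned on published late-life-breeding selection
#' experiments: two long-term experiments with five or four replicate
#' populations per regime, one short-term experiment with three, and one
#' diet-structured experiment (three larval diets, two replicates per
#' regime and diet). Control lineages breed early and often, so they
#' accumulate more elapsed generations than the late-breeding selected
#' lineages kept for the same wall-clock time; the generation numbers encode
#' that asymmetry. Effective sizes and generation counts are package
#' defaults chosen to be realistic for laboratory Drosophila populations and
#' are documented in the methods vignette.
#'
#' @return A list with `populations` (row-bound design tibble for all four
#'   studies) and `parameters` (one row per study: `ne_control`,
#'   `ne_selected`, `gen_control`, `gen_selected`, `breeding_fraction`).
#' @export
default_study_designs <- function() {
  populations <- bind_rows(
    study_design("CarnesLike", n_control = 5, n_selected = 5, pool_size = 200),
    study_design("FabianLike", n_control = 4, n_selected = 4, pool_size = 250),
    study_design("HoedjesLike", n_control = 2, n_selected = 2,
                 diets = c("low", "medium", "high"), pool_size = 125),
    study_design("RemolinaLike", n_control = 3, n_selected = 3, pool_size = 100)
  )
  parameters <- tibble(
    study = c("CarnesLike", "FabianLike", "HoedjesLike", "RemolinaLike"),
    ne_control = c(1000L, 200L, 250L, 500L),
    ne_selected = c(1000L, 200L, 250L, 500L),
    gen_control = c(400L, 300L, 116L, 100L),
    gen_selected = c(170L, 100L, 58L, 50L),
    breeding_fraction = c(0.5, 0.25, 0.5, 0.5)
  )
  list(populations = populations, parameters = parameters)
}

# TRUE when the design has a real diet treatment (more than the 'none' level)
has_diet_structure <- function(design) {
  any(design$diet != "none") && length(unique(design$diet)) >= 2
}
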