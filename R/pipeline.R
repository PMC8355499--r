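# End-to-end pipeline driver: wires the synthetic generator and the
# analysis stages into reproducible, seeded runs with a hashed artifact
# manifest.

#' Read a pipeline configuration file
#'
#' YAML schema: top-level `n_families`, optional `effects`
#' (`n_s_gt_c`, `n_c_gt_s`, `delta`), optional `thresholds` (`alpha`,
#' `delta_min`, `fdr`, `window`, `n_sims`) and a `studies` list, each entry
#' with `name`, `n_control`, `n_selected`, optional `diets`, `pool_size`,
#' `ne_control`, `ne_selected`, `gen_control`, `gen_selected`,
#' `breeding_fraction`. Omitted thresholds default to the standard analysis
#' values (alpha 0.01, delta_min 0.3, fdr 0.05, window 1000, n_sims 5000).
#'
#' @param path Path to a YAML config file.
#' @return A validated config list with `populations` and `parameters`
#'   tibbles attached.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file does not exist: ", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$studies) || length(cfg$studies) == 0) {
    abort("config must declare at least one study")
  }
  defaults <- list(alpha = 0.01, delta_min = 0.3, fdr = 0.05,
                   window = 1000, n_sims = 5000)
  cfg$thresholds <- utils::modifyList(defaults, cfg$thresholds %||% list())
  cfg$effects <- utils::modifyList(
    list(n_s_gt_c = 0, n_c_gt_s = 0, delta = 1.0), cfg$effects %||% list()
  )
  cfg$n_families <- cfg$n_families %||% 100
  pops <- purrr::map_dfr(cfg$studies, function(st) {
    study_design(st$name, st$n_control, st$n_selected,
                 diets = unlist(st$diets %||% "none"),
                 pool_size = st$pool_size %||% 125)
  })
  params <- purrr::map_dfr(cfg$studies, function(st) {
    tibble(
      study = st$name,
      ne_control = as.integer(st$ne_control %||% 500),
      ne_selected = as.integer(st$ne_selected %||% 500),
      gen_control = as.integer(st$gen_control %||% 100),
      gen_selected = as.integer(st$gen_selected %||% 50),
      breeding_fraction = st$breeding_fraction %||% 1
    )
  })
  cfg$populations <- validate_design(pops)
  cfg$parameters <- params
  cfg
}

`%||%` <- function(x, y) if (is.null(x)) y else x

pipeline_stages <- c("simulate", "abundance", "frequency", "drift",
                     "overlap", "report")

stage_inputs <- list(
  simulate = character(),
  abundance = c("coverage_%s.tsv"),
  frequency = c("insertions_%s.tsv", "genes.gff3"),
  drift = c("classification1_%s.tsv", "reference_frequencies.tsv"),
  overlap = c("classification1_%s.tsv"),
  report = c("classification1_%s.tsv")
)

#' Run the televolve pipeline
#'
#' Executes the requested stages in dependency order against one output
#' directory: `simulate` writes the synthetic study inputs (coverage,
#' insertion tables, hierarchy, gene annotation, reference frequencies),
#' `abundance` the three classification approaches, `frequency` the
#' segregating-frequency analyses, `drift` the Wright-Fisher neutrality
#' tests, `overlap` the cross-study sharing statistics, and `report` a
#' consolidated summary. Requesting a stage whose inputs are missing is an
#' error naming the stage to run first. Reruns with the same config and
#' seed are byte-identical; every output is listed in `manifest.tsv` with
#' its MD5 hash.
#'
#' @param config Path to a YAML config file or a list from
#'   [read_pipeline_config()].
#' @param stages Subset of `simulate`, `abundance`, `frequency`, `drift`,
#'   `overlap`, `report` (default: all).
#' @param seed Integer seed governing every stochastic stage.
#' @param out_dir Output directory (created if missing).
#' @return The manifest tibble (`stage`, `file`, `md5`), invisibly.
#' @export
run_pipeline <- function(config, stages = pipeline_stages, seed = 1,
                         out_dir = ".") {
  if (is.character(config)) config <- read_pipeline_config(config)
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  stages <- pipeline_stages[pipeline_stages %in% stages]
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  studies <- unique(config$populations$study)
  path_of <- function(f) file.path(out_dir, f)
  check_inputs <- function(stage) {
    needed <- unlist(purrr::map(stage_inputs[[stage]], function(tmpl) {
      if (grepl("%s", tmpl)) sprintf(tmpl, studies) else tmpl
    }))
    missing <- needed[!file.exists(path_of(needed))]
    if (length(missing) > 0) {
      prereq <- if (stage %in% c("abundance", "frequency")) "simulate"
                else "abundance"
      abort(paste0("stage '", stage, "' is missing input(s) ",
                   paste(missing, collapse = ", "),
                   "; run stage '", prereq, "' first"))
    }
  }
  written <- tibble(stage = character(), file = character())
  note <- function(stage, files) {
    written <<- bind_rows(written, tibble(stage = stage, file = files))
  }
  th <- config$thresholds

  for (stage in stages) {
    check_inputs(stage)
    if (stage == "simulate") {
      files <- run_stage_simulate(config, seed, path_of, studies)
    } else if (stage == "abundance") {
      files <- run_stage_abundance(config, path_of, studies, th)
    } else if (stage == "frequency") {
      files <- run_stage_frequency(config, path_of, studies, th)
    } else if (stage == "drift") {
      files <- run_stage_drift(config, seed, path_of, studies, th)
    } else if (stage == "overlap") {
      files <- run_stage_overlap(config, path_of, studies)
    } else {
      files <- run_stage_report(path_of, studies, seed)
    }
    note(stage, files)
  }
  manifest <- written %>%
    mutate(md5 = unname(tools::md5sum(path_of(.data$file))))
  readr::write_tsv(manifest, path_of("manifest.tsv"))
  inform(paste0("pipeline complete: ", nrow(manifest), " artifact(s), seed ",
                seed))
  invisible(manifest)
}

run_stage_simulate <- function(config, seed, path_of, studies) {
  files <- character()
  truth0 <- sample_reference_families(config$n_families, seed = seed)
  truth0 <- plant_effects(truth0, config$effects$n_s_gt_c,
                          config$effects$n_c_gt_s,
                          delta = config$effects$delta)
  hierarchy <- truth0 %>%
    select("family", "subclass", "te_class", "consensus_length")
  write_te_hierarchy(hierarchy, path_of("hierarchy.tsv"))
  files <- c(files, "hierarchy.tsv")
  readr::write_tsv(config$populations, path_of("design.tsv"))
  files <- c(files, "design.tsv")
  # shared reference frequencies (the natural-population analogue)
  write_results_table(
    truth0 %>% select("family", p0 = "mean_freq", "n_sites"),
    path_of("reference_frequencies.tsv")
  )
  files <- c(files, "reference_frequencies.tsv")
  genes <- synth_genes(seed)
  write_gene_intervals(genes, path_of("genes.gff3"))
  files <- c(files, "genes.gff3")
  for (st in studies) {
    d <- config$populations %>% filter(.data$study == st)
    cov <- generate_coverage_data(truth0, d, seed = substream_seed(seed, st))
    write_coverage_table(cov, path_of(sprintf("coverage_%s.tsv", st)))
    ins <- generate_insertion_data(truth0, d,
                                   seed = substream_seed(seed, st))
    write_insertion_table(ins, path_of(sprintf("insertions_%s.tsv", st)))
    files <- c(files, sprintf(c("coverage_%s.tsv", "insertions_%s.tsv"), st))
  }
  files
}

synth_genes <- function(seed, n_per_chrom = 40) {
  with_substream(seed, "genes", {
    purrr::map_dfr(paste0("chr", 1:5), function(ch) {
      start <- sort(sample.int(2e7 - 20000, n_per_chrom))
      tibble(
        gene_id = sprintf("g_%s_%03d", ch, seq_len(n_per_chrom)),
        chromosome = ch, start = start,
        end = start + sample(500:15000, n_per_chrom, replace = TRUE),
        strand = sample(c("+", "-"), n_per_chrom, replace = TRUE)
      )
    })
  })
}

read_design_file <- function(path_of) {
  validate_design(readr::read_tsv(path_of("design.tsv"),
                                  show_col_types = FALSE))
}

run_stage_abundance <- function(config, path_of, studies, th) {
  design <- read_design_file(path_of)
  hierarchy <- read_te_hierarchy(path_of("hierarchy.tsv"))
  files <- character()
  all_abund <- list()
  for (st in studies) {
    d <- design %>% filter(.data$study == st)
    cov <- read_coverage_table(path_of(sprintf("coverage_%s.tsv", st)),
                               hierarchy)
    retained <- filter_families(cov)
    abund <- estimate_abundance(cov, retained)
    all_abund[[st]] <- mutate(abund, study = st)
    write_results_table(abund, path_of(sprintf("abundance_%s.tsv", st)))
    c1 <- classify_approach1(cov, d, alpha = th$alpha,
                             delta_min = th$delta_min, retained = retained)
    write_results_table(as_tibble(c1),
                        path_of(sprintf("classification1_%s.tsv", st)))
    c3 <- classify_approach3(abund, d)
    write_results_table(as_tibble(c3),
                        path_of(sprintf("classification3_%s.tsv", st)))
    files <- c(files, sprintf(c("abundance_%s.tsv", "classification1_%s.tsv",
                                "classification3_%s.tsv"), st))
  }
  if (length(studies) >= 2) {
    c2 <- classify_approach2(bind_rows(all_abund), design, fdr = th$fdr)
    write_results_table(as_tibble(c2),
                        path_of("classification2_combined.tsv"))
    files <- c(files, "classification2_combined.tsv")
  }
  files
}

run_stage_frequency <- function(config, path_of, studies, th) {
  design <- read_design_file(path_of)
  genes <- read_gene_intervals(path_of("genes.gff3"))
  files <- character()
  for (st in studies) {
    d <- design %>% filter(.data$study == st)
    sites <- read_insertion_table(path_of(sprintf("insertions_%s.tsv", st)),
                                  d$sample)
    fmf <- family_mean_frequency(sites)
    write_results_table(fmf, path_of(sprintf("family_frequency_%s.tsv", st)))
    st_res <- suppressMessages(site_differentiation_test(sites, d))
    ann <- annotate_sites(st_res %>% filter(.data$significant), genes,
                          window = th$window)
    out <- as_tibble(st_res) %>%
      left_join(ann, by = c("chrom", "pos", "family"))
    write_results_table(out, path_of(sprintf("site_tests_%s.tsv", st)))
    fam <- family_frequency_regime_test(sites, d, fdr = th$fdr)
    write_results_table(fam, path_of(sprintf("family_freq_tests_%s.tsv", st)))
    files <- c(files, sprintf(c("family_frequency_%s.tsv",
                                "site_tests_%s.tsv",
                                "family_freq_tests_%s.tsv"), st))
  }
  files
}

run_stage_drift <- function(config, seed, path_of, studies, th) {
  ref <- readr::read_tsv(path_of("reference_frequencies.tsv"),
                         show_col_types = FALSE)
  params <- config$parameters
  rows <- purrr::map_dfr(studies, function(st) {
    cl <- readr::read_tsv(path_of(sprintf("classification1_%s.tsv", st)),
                          show_col_types = FALSE)
    pr <- params %>% filter(.data$study == st)
    d <- config$populations %>% filter(.data$study == st)
    cfg <- drift_config(
      ref %>% rename(p0 = dplyr::any_of("mean_freq")),
      ne_control = pr$ne_control, ne_selected = pr$ne_selected,
      gen_control = pr$gen_control, gen_selected = pr$gen_selected,
      n_rep_control = sum(d$regime == "C"),
      n_rep_selected = sum(d$regime == "S"),
      breeding_fraction = pr$breeding_fraction,
      n_sims = th$n_sims, seed = substream_seed(seed, paste0("drift/", st))
    )
    sims <- simulate_drift(cfg)
    obs_s <- sum(cl$label == "S>C"); obs_c <- sum(cl$label == "C>S")
    if (obs_s + obs_c == 0) {
      return(tibble(study = st, observed_sgtc = obs_s, observed_cgts = obs_c,
                    observed_statistic = NA_real_, p_mean = NA_real_,
                    p_consistent = NA_real_, n_sims = th$n_sims))
    }
    res_mean <- neutrality_pvalue(sims, obs_s, obs_c, variant = "mean")
    res_con <- neutrality_pvalue(sims, obs_s, obs_c, variant = "consistent")
    tibble(study = st, observed_sgtc = obs_s, observed_cgts = obs_c,
           observed_statistic = res_mean$observed_statistic,
           p_mean = res_mean$p.value, p_consistent = res_con$p.value,
           n_sims = th$n_sims)
  })
  write_results_table(rows, path_of("drift_summary.tsv"))
  "drift_summary.tsv"
}

read_classifications <- function(path_of, studies) {
  purrr::map_dfr(studies, function(st) {
    readr::read_tsv(path_of(sprintf("classification1_%s.tsv", st)),
                    show_col_types = FALSE) %>%
      mutate(study = st)
  })
}

run_stage_overlap <- function(config, path_of, studies) {
  if (length(studies) < 2) return(character())
  cl <- read_classifications(path_of, studies)
  ov <- cross_study_overlaps(cl)
  write_results_table(ov, path_of("overlaps.tsv"))
  fc <- pairwise_fc_correlation(cl)
  write_results_table(fc, path_of("fc_correlations.tsv"))
  c("overlaps.tsv", "fc_correlations.tsv")
}

run_stage_report <- function(path_of, studies, seed) {
  cl <- read_classifications(path_of, studies)
  summary_tbl <- cl %>%
    group_by(.data$study) %>%
    summarise(
      n_families = dplyr::n(),
      n_sgtc = sum(.data$label == "S>C"),
      n_cgts = sum(.data$label == "C>S"),
      pct_sgtc = 100 * mean(.data$label == "S>C"),
      pct_cgts = 100 * mean(.data$label == "C>S"),
      .groups = "drop"
    )
  write_results_table(summary_tbl, path_of("summary.tsv"))
  lines <- c(
    "# televolve pipeline report",
    "",
    paste0("Seed: ", seed),
    "",
    "## TE families classified per study (approach #1)",
    "",
    paste0("| study | N | S>C | C>S | %S>C | %C>S |"),
    paste0("|---|---|---|---|---|---|"),
    sprintf("| %s | %d | %d | %d | %.1f | %.1f |",
            summary_tbl$study, summary_tbl$n_families, summary_tbl$n_sgtc,
            summary_tbl$n_cgts, summary_tbl$pct_sgtc, summary_tbl$pct_cgts)
  )
  if (file.exists(path_of("drift_summary.tsv"))) {
    dr <- readr::read_tsv(path_of("drift_summary.tsv"),
                          show_col_types = FALSE)
    lines <- c(lines, "", "## Drift neutrality tests", "",
               sprintf("- %s: observed S>C proportion %.3f, p(mean) = %s",
                       dr$study, dr$observed_statistic,
                       format(dr$p_mean, digits = 3)))
  }
  writeLines(lines, path_of("report.md"))
  c("summary.tsv", "report.md")
}
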