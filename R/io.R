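# Readers and writers for the plain-text tables the pipeline exchanges.
# All tables are UTF-8, tab-separated; missing values are written as the
# literal token NA (never "."); coordinates follow TE_COORDINATE_SYSTEM.

read_tsv_strict <- function(path, col_types) {
  if (!file.exists(path)) abort(paste0("file does not exist: ", path))
  out <- suppressWarnings(
    readr::read_tsv(path, col_types = col_types, progress = FALSE, na = "NA")
  )
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    abort(paste0(
      "malformed row in ", path, " at line ", probs$row[1],
      ": expected ", probs$expected[1], ", got ", probs$actual[1]
    ))
  }
  out
}

#' Read a TE hierarchy table
#'
#' The hierarchy maps every TE family to its subclass (LTR, non-LTR, TIR or
#' other) and class (RNA for retrotransposons, DNA for DNA transposons), plus
#' the length of the family consensus sequence. Columns: `name`, `subclass`,
#' `class`, `length`.
#'
#' @param path Path to a tab-separated hierarchy file.
#' @return A tibble with columns `family`, `subclass`, `te_class`,
#'   `consensus_length`.
#' @export
read_te_hierarchy <- function(path) {
  raw <- read_tsv_strict(path, readr::cols(
    name = readr::col_character(), subclass = readr::col_character(),
    class = readr::col_character(), length = readr::col_integer()
  ))
  validate_hierarchy(tibble(
    family = raw$name, subclass = raw$subclass,
    te_class = raw$class, consensus_length = raw$length
  ))
}

#' Validate a TE hierarchy tibble
#'
#' Enforces the biological label invariants: LTR and non-LTR families are
#' RNA-class retrotransposons, TIR families are DNA-class transposons, family
#' names are unique and consensus lengths positive.
#'
#' @param hierarchy Tibble with columns `family`, `subclass`, `te_class`,
#'   `consensus_length`.
#' @return The validated tibble.
#' @export
validate_hierarchy <- function(hierarchy) {
  h <- as_tibble(hierarchy)
  if (anyDuplicated(h$family) > 0) abort("duplicate family name in hierarchy")
  if (!all(h$subclass %in% c("LTR", "non-LTR", "TIR", "other"))) {
    abort("subclass must be one of LTR, non-LTR, TIR, other")
  }
  if (!all(h$te_class %in% c("RNA", "DNA"))) {
    abort("class must be RNA or DNA")
  }
  bad_rna <- h$subclass %in% c("LTR", "non-LTR") & h$te_class != "RNA"
  if (any(bad_rna)) {
    abort(paste0("family '", h$family[bad_rna][1],
                 "': LTR/non-LTR subclasses must be RNA class"))
  }
  bad_tir <- h$subclass == "TIR" & h$te_class != "DNA"
  if (any(bad_tir)) {
    abort(paste0("family '", h$family[bad_tir][1],
                 "': TIR subclass must be DNA class"))
  }
  if (any(h$consensus_length <= 0)) abort("consensus_length must be > 0")
  h
}

#' Write a TE hierarchy table
#' @param hierarchy Validated hierarchy tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_te_hierarchy <- function(hierarchy, path) {
  h <- validate_hierarchy(hierarchy)
  readr::write_tsv(
    tibble(name = h$family, subclass = h$subclass, class = h$te_class,
           length = h$consensus_length),
    path, na = "NA"
  )
  invisible(path)
}

#' Read a per-position normalised TE coverage table
#'
#' Coverage profiles hold, for every TE family, population sample and 1-based
#' consensus position, the coverage-normalised insertion estimate (insertions
#' per haploid genome supported at that position). Columns: `family`,
#' `sample`, `pos`, `insertions`.
#'
#' @param path Path to a tab-separated coverage file.
#' @param hierarchy Optional hierarchy tibble; when given, families absent
#'   from it are reported with a warning and positions are checked against
#'   the consensus length.
#' @return A validated coverage tibble.
#' @export
read_coverage_table <- function(path, hierarchy = NULL) {
  cov <- read_tsv_strict(path, readr::cols(
    family = readr::col_character(), sample = readr::col_character(),
    pos = readr::col_integer(), insertions = readr::col_double()
  ))
  validate_coverage(cov, hierarchy)
}

#' Validate a coverage tibble
#' @param coverage Tibble with columns `family`, `sample`, `pos`, `insertions`.
#' @param hierarchy Optional hierarchy tibble (see [read_coverage_table()]).
#' @return The validated tibble.
#' @export
validate_coverage <- function(coverage, hierarchy = NULL) {
  cov <- as_tibble(coverage)
  if (any(is.na(cov$pos)) || any(cov$pos < 1)) {
    abort("position must be >= 1 (coordinates are 1-based)")
  }
  if (any(is.na(cov$insertions)) || any(cov$insertions < 0)) {
    abort("insertion estimates must be non-negative")
  }
  if (anyDuplicated(paste(cov$family, cov$sample, cov$pos)) > 0) {
    abort("duplicate (family, sample, pos) entry in coverage table")
  }
  if (!is.null(hierarchy)) {
    unknown <- setdiff(unique(cov$family), hierarchy$family)
    if (length(unknown) > 0) {
      warn(paste0("coverage table contains ", length(unknown),
                  " family/families not in the hierarchy: ",
                  paste(head(unknown, 5), collapse = ", ")))
    }
    lim <- cov %>%
      left_join(hierarchy[, c("family", "consensus_length")], by = "family") %>%
      filter(!is.na(.data$consensus_length), .data$pos > .data$consensus_length)
    if (nrow(lim) > 0) {
      abort(paste0("position beyond consensus length for family '",
                   lim$family[1], "'"))
    }
  }
  cov
}

#' Write a coverage table
#' @param coverage Validated coverage tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_table <- function(coverage, path) {
  cov <- validate_coverage(coverage)
  readr::write_tsv(cov[, c("family", "sample", "pos", "insertions")], path,
                   na = "NA")
  invisible(path)
}

#' Read a genomic TE insertion table
#'
#' Insertion tables locate individual TE insertions on the genome and give
#' their population frequency in every sequenced pool. On disk the dialect is
#' wide: columns `chrom`, `pos`, `family` followed by one `freq_<sample>`
#' column per declared sample. In memory televolve uses the long (tidy)
#' layout: one row per site and sample with columns `chrom`, `pos`, `family`,
#' `sample`, `freq`. A site not detected in a population carries an `NA`
#' frequency and is excluded from tests requiring that population.
#'
#' @param path Path to a tab-separated insertion file.
#' @param samples Character vector of sample names; one `freq_<sample>`
#'   column per entry must be present.
#' @return A validated long-format insertion tibble.
#' @export
read_insertion_table <- function(path, samples) {
  if (!file.exists(path)) abort(paste0("file does not exist: ", path))
  freq_cols <- paste0("freq_", samples)
  spec <- c(
    list(chrom = readr::col_character(), pos = readr::col_integer(),
         family = readr::col_character()),
    setNames(rep(list(readr::col_double()), length(freq_cols)), freq_cols)
  )
  wide <- read_tsv_strict(path, do.call(readr::cols, spec))
  miss <- setdiff(freq_cols, names(wide))
  if (length(miss) > 0) {
    abort(paste0("missing frequency column(s): ", paste(miss, collapse = ", ")))
  }
  long <- wide %>%
    tidyr::pivot_longer(dplyr::all_of(freq_cols), names_to = "sample",
                        values_to = "freq", names_prefix = "freq_") %>%
    mutate(sample = factor(.data$sample, levels = samples)) %>%
    arrange(.data$chrom, .data$pos, .data$family, .data$sample) %>%
    mutate(sample = as.character(.data$sample))
  validate_insertions(long)
}

#' Validate a long-format insertion tibble
#' @param sites Tibble with columns `chrom`, `pos`, `family`, `sample`, `freq`.
#' @return The validated tibble.
#' @export
validate_insertions <- function(sites) {
  s <- as_tibble(sites)
  if (any(s$pos < 1)) abort("position must be >= 1 (coordinates are 1-based)")
  bad <- !is.na(s$freq) & (s$freq < 0 | s$freq > 1)
  if (any(bad)) {
    abort(paste0("frequency outside [0, 1] at ", s$chrom[bad][1], ":",
                 s$pos[bad][1]))
  }
  if (anyDuplicated(paste(s$chrom, s$pos, s$family, s$sample)) > 0) {
    abort("duplicate (chrom, pos, family) entry for a sample")
  }
  s
}

#' Write an insertion table (wide dialect)
#' @param sites Long-format insertion tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_insertion_table <- function(sites, path) {
  s <- validate_insertions(sites)
  wide <- s %>%
    mutate(sample = paste0("freq_", .data$sample)) %>%
    tidyr::pivot_wider(names_from = "sample", values_from = "freq") %>%
    arrange(.data$chrom, .data$pos, .data$family)
  readr::write_tsv(wide, path, na = "NA")
  invisible(path)
}

#' Read gene intervals from a GFF3 file
#'
#' Only rows of type `gene` are used; other feature rows are skipped and
#' their count reported. Coordinates are 1-based inclusive as in the GFF3
#' standard.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `chromosome`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_intervals <- function(path) {
  if (!file.exists(path)) abort(paste0("file does not exist: ", path))
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading GFF3 requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  is_gene <- as.character(gr$type) == "gene"
  n_skipped <- sum(!is_gene)
  if (n_skipped > 0) {
    inform(paste0("skipped ", n_skipped, " non-gene feature row(s)"))
  }
  gr <- gr[is_gene]
  out <- tibble(
    gene_id = as.character(gr$ID),
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  validate_gene_intervals(out)
}

#' Validate a gene interval tibble
#' @param genes Tibble with columns `gene_id`, `chromosome`, `start`, `end`,
#'   `strand`.
#' @return The validated tibble.
#' @export
validate_gene_intervals <- function(genes) {
  g <- as_tibble(genes)
  if (any(is.na(g$gene_id) | g$gene_id == "")) abort("gene_id must be non-empty")
  if (any(is.na(g$chromosome) | g$chromosome == "")) {
    abort("chromosome must be non-empty")
  }
  if (any(g$end < g$start)) abort("gene end must be >= start")
  if (!all(g$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  g
}

#' Write gene intervals as GFF3
#' @param genes Validated gene interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_intervals <- function(genes, path) {
  g <- validate_gene_intervals(genes)
  lines <- c(
    "##gff-version 3",
    sprintf("%s\ttelevolve\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            g$chromosome, g$start, g$end, g$strand, g$gene_id)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a generic results table
#'
#' Deterministic TSV writer used for all derived outputs: rows are sorted by
#' the non-numeric key columns (then numeric columns), and floating point
#' values are formatted at six significant digits so reruns are byte
#' identical.
#'
#' @param records A data frame of homogeneous records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  df <- as_tibble(records)
  dir <- dirname(path)
  if (!dir.exists(dir)) abort(paste0("directory does not exist: ", dir))
  keys <- names(df)[!vapply(df, is.numeric, logical(1))]
  ord_cols <- c(keys, setdiff(names(df), keys))
  if (length(ord_cols) > 0) {
    df <- df[do.call(order, df[ord_cols]), , drop = FALSE]
  }
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  readr::write_tsv(df, path, na = "NA")
  invisible(path)
}
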