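# Segregating-frequency analytics: family means, group comparisons,
# abundance-frequency coupling, per-site and per-family regime tests,
# and gene-proximity annotation.

test_that("family mean frequency averages non-NA sites per population", {
  one <- sites_from_matrix(matrix(0.4, 1, 1, dimnames = list(NULL, "s1")))
  expect_equal(family_mean_frequency(one)$mean_freq, 0.4)
  two <- sites_from_matrix(matrix(c(0.2, 0.6), 2, 1,
                                  dimnames = list(NULL, "s1")))
  expect_equal(family_mean_frequency(two)$mean_freq, 0.4)
  # NA site ignored; all-NA population absent
  m <- matrix(c(0.2, NA, NA, NA), 2, 2, dimnames = list(NULL, c("s1", "s2")))
  res <- family_mean_frequency(sites_from_matrix(m))
  expect_equal(res$sample, "s1")
  expect_equal(res$mean_freq, 0.2)
  expect_equal(res$n_sites, 1L)
  # brute-force mean on a random table
  set.seed(19)
  big <- matrix(runif(60), 20, 3, dimnames = list(NULL, c("s1", "s2", "s3")))
  got <- family_mean_frequency(sites_from_matrix(big))
  expect_equal(got$mean_freq, unname(colMeans(big)), tolerance = 1e-12)
  # removing a site keeps the mean within the remaining range
  drop1 <- family_mean_frequency(sites_from_matrix(big[-1, , drop = FALSE]))
  expect_true(all(drop1$mean_freq >= apply(big[-1, ], 2, min) &
                    drop1$mean_freq <= apply(big[-1, ], 2, max)))
})

test_that("group frequency comparison separates planted Beta groups", {
  set.seed(91)
  cl <- tibble::tibble(
    family = paste0("f", 1:30),
    label = rep(c("C>S", "S>C"), each = 15),
    log2fc = c(-runif(15, 0.5, 2), runif(15, 0.5, 2)),
    delta_insertion = 0
  )
  freqs <- tibble::tibble(
    family = cl$family,
    freq = c(rbeta(15, 1, 9), rbeta(15, 3, 3))
  )
  res <- frequency_group_comparison(freqs, cl)
  expect_lt(res$p.value, 0.05)
  expect_lt(res$estimate, 0) # C>S group at lower frequency
  # top_n larger than the groups falls back to the whole group
  res_all <- frequency_group_comparison(freqs, cl, top_n = 100)
  expect_equal(res_all$p.value, res$p.value)
  # top_n restriction is deterministic and uses |log2fc| ranking
  res_top <- frequency_group_comparison(freqs, cl, top_n = 5)
  expect_false(isTRUE(all.equal(res_top$p.value, res$p.value)))
  expect_identical(res_top,
                   frequency_group_comparison(freqs, cl, top_n = 5))
})

test_that("abundance-frequency correlation recovers the generator target", {
  des <- tiny_design()
  truth <- sample_reference_families(150, target_rho = -0.5, seed = 47)
  cov <- generate_coverage_data(truth, des, seed = 47)
  sites <- generate_insertion_data(truth, des, seed = 47)
  ab <- estimate_abundance(cov)
  fmf <- family_mean_frequency(sites)
  res <- abundance_frequency_correlation(ab, fmf)
  expect_gte(res$estimate, -0.65)
  expect_lte(res$estimate, -0.35)
  expect_lt(res$p.value, 0.001)
  # per-population variant returns one row per sample
  per_pop <- abundance_frequency_correlation(ab, fmf, by = "population")
  expect_equal(nrow(per_pop), nrow(des))
  # uncoupled truth: small correlation
  t0 <- sample_reference_families(150, coupling = 0, seed = 48)
  ab0 <- estimate_abundance(generate_coverage_data(t0, des, seed = 48))
  f0 <- family_mean_frequency(generate_insertion_data(t0, des, seed = 48))
  expect_lt(abs(abundance_frequency_correlation(ab0, f0)$estimate), 0.2)
  # perfect monotone inverse
  abx <- tibble::tibble(family = paste0("f", 1:5), sample = "s1",
                        insertions = 1:5)
  fx <- tibble::tibble(family = paste0("f", 1:5), sample = "s1",
                       mean_freq = c(0.9, 0.7, 0.5, 0.3, 0.1), n_sites = 1L)
  expect_equal(abundance_frequency_correlation(abx, fx)$estimate, -1)
})

test_that("site differentiation applies the Bonferroni rule over tested sites", {
  des <- study_design("F", 3, 3)
  truth <- sample_reference_families(30, seed = 53)
  sites <- generate_insertion_data(truth, des, seed = 53)
  res <- site_differentiation_test(sites, des)
  n_tested <- attr(res, "n_tested")
  expect_equal(attr(res, "threshold"), 0.05 / n_tested)
  # identical frequencies across populations: nothing significant
  m <- matrix(0.4, 20, 6, dimnames = list(NULL, des$sample))
  flat <- suppressMessages(site_differentiation_test(
    sites_from_matrix(m), des
  ))
  expect_true(all(!flat$significant))
  # a planted strong shift is found and oriented
  shifted <- m
  shifted[1, des$regime == "S"] <- 0.95
  set.seed(3)
  shifted <- pmin(pmax(shifted + rnorm(length(shifted), 0, 0.01), 0), 1)
  res2 <- suppressMessages(site_differentiation_test(
    sites_from_matrix(shifted), des
  ))
  hit <- res2[res2$pos == 100, ]
  expect_true(hit$significant)
  expect_equal(hit$direction, "S")
  expect_true(all(!res2$significant[res2$pos != 100]))
})

test_that("sites lacking two populations per regime are skipped", {
  des <- tiny_design()
  m <- matrix(c(0.5, 0.5, NA, 0.5,
                0.4, 0.4, 0.4, 0.4), 2, 4, byrow = TRUE,
              dimnames = list(NULL, des$sample))
  expect_message(res <- site_differentiation_test(sites_from_matrix(m), des),
                 "skipped 1")
  expect_equal(attr(res, "n_skipped"), 1L)
})

test_that("family frequency test flags planted family-wide shifts at FDR", {
  des <- study_design("F", 3, 3)
  truth <- sample_reference_families(25, seed = 59)
  truth$freq_delta[truth$family == "TE001"] <- 0.2
  sites <- generate_insertion_data(truth, des, seed = 59)
  res <- family_frequency_regime_test(sites, des)
  expect_true(res$significant[res$family == "TE001"])
  # BH discoveries are a subset of raw p < 0.05
  expect_true(all(res$p_adjusted >= res$p_regime, na.rm = TRUE))
  expect_true(all(res$p_regime[res$significant] < 0.05))
  # intersection with an abundance classification
  cl <- tibble::tibble(family = truth$family,
                       label = ifelse(truth$family == "TE001", "S>C", "NS"),
                       log2fc = 0, delta_insertion = 0)
  res2 <- family_frequency_regime_test(sites, des, classification = cl)
  expect_true(res2$joint_significant[res2$family == "TE001"])
  expect_true(all(!res2$joint_significant[res2$family != "TE001"]))
})

test_that("gene annotation follows the inclusive 1-kb window and strand", {
  genes <- gene_tbl(gene_id = "g1", chromosome = "chr1", start = 100L,
                    end = 200L, strand = "+")
  site <- function(pos) tibble::tibble(chrom = "chr1", pos = pos,
                                       family = "TE001", sample = "s",
                                       freq = 0.5)
  expect_equal(annotate_sites(site(150L), genes)$relation, "inside")
  expect_equal(annotate_sites(site(100L), genes)$relation, "inside")
  expect_equal(annotate_sites(site(200L), genes)$relation, "inside")
  # exactly 1000 bp away is still annotated (inclusive boundary)
  down <- annotate_sites(site(1200L), genes)
  expect_equal(down$relation, "downstream")
  expect_equal(down$distance, 1000)
  expect_equal(annotate_sites(site(1201L), genes)$relation, "intergenic")
  up <- annotate_sites(site(50L), genes)
  expect_equal(up$relation, "upstream")
  # minus strand flips the labels
  gminus <- dplyr::mutate(genes, strand = "-")
  expect_equal(annotate_sites(site(1200L), gminus)$relation, "upstream")
  expect_equal(annotate_sites(site(50L), gminus)$relation, "downstream")
  # unknown chromosome: intergenic
  far <- tibble::tibble(chrom = "chrX", pos = 150L, family = "TE001",
                        sample = "s", freq = 0.5)
  expect_equal(annotate_sites(far, genes)$relation, "intergenic")
})

test_that("annotation picks the nearest gene and breaks ties by id", {
  genes <- gene_tbl(
    gene_id = c("gB", "gA"), chromosome = "chr1",
    start = c(2000L, 4000L), end = c(2500L, 4500L),
    strand = c("+", "+")
  )
  near <- annotate_sites(tibble::tibble(chrom = "chr1", pos = 3000L,
                                        family = "f", sample = "s",
                                        freq = 0.1), genes)
  expect_equal(near$gene_id, "gB") # 500 bp vs 1000 bp
  tie <- annotate_sites(tibble::tibble(chrom = "chr1", pos = 3250L,
                                       family = "f", sample = "s",
                                       freq = 0.1), genes)
  expect_equal(tie$gene_id, "gA") # equidistant (750), lexicographic
})

test_that("annotation is strand-symmetric under coordinate reflection", {
  set.seed(67)
  L <- 100000L
  genes <- gene_tbl(
    gene_id = sprintf("g%02d", 1:8), chromosome = "chr1",
    start = as.integer(sort(sample.int(L - 5000L, 8))),
    end = 0L, strand = sample(c("+", "-"), 8, replace = TRUE)
  )
  genes$end <- genes$start + sample(200:3000, 8)
  sites <- tibble::tibble(
    chrom = "chr1", pos = as.integer(sample.int(L, 120)),
    family = "f", sample = "s", freq = 0.5
  )
  fwd <- annotate_sites(sites, genes)
  refl_genes <- genes %>%
    dplyr::mutate(start2 = L + 1L - end, end2 = L + 1L - start,
                  strand = ifelse(strand == "+", "-", "+")) %>%
    dplyr::mutate(start = start2, end = end2) %>%
    dplyr::select(gene_id, chromosome, start, end, strand)
  refl_sites <- dplyr::mutate(sites, pos = L + 1L - pos)
  rev <- annotate_sites(refl_sites, refl_genes) %>%
    dplyr::mutate(pos = L + 1L - pos) %>%
    dplyr::arrange(pos)
  fwd <- dplyr::arrange(fwd, pos)
  expect_equal(fwd$relation, rev$relation)
  expect_equal(fwd$gene_id, rev$gene_id)
  expect_equal(fwd$distance, rev$distance)
})
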