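# Family filter, abundance estimation, the three classification
# approaches, fold changes, content models, enrichment and the
# copy-number count correction.

test_that("retention filter applies the 80%-of-positions rule inclusively", {
  mk <- function(vals) {
    tibble::tibble(family = "TE001", sample = "s1",
                   pos = seq_along(vals), insertions = vals)
  }
  expect_equal(filter_families(mk(rep(0.6, 10))), "TE001")
  expect_equal(filter_families(mk(c(rep(0.6, 7), rep(0.1, 3)))), character(0))
  # exactly 80% counts as retained
  expect_equal(filter_families(mk(c(rep(0.6, 8), rep(0.1, 2)))), "TE001")
  # exactly 0.5 at a position counts as covered
  expect_equal(filter_families(mk(rep(0.5, 5))), "TE001")
  # the rule averages across populations before thresholding
  two_pop <- dplyr::bind_rows(
    tibble::tibble(family = "TE002", sample = "s1", pos = 1:5,
                   insertions = 0.9),
    tibble::tibble(family = "TE002", sample = "s2", pos = 1:5,
                   insertions = 0.2)
  )
  expect_equal(filter_families(two_pop), "TE002") # average 0.55 >= 0.5
})

test_that("abundance estimate is the per-position mean", {
  cov <- tibble::tibble(family = "TE001", sample = "s1", pos = 1:3,
                        insertions = c(1, 2, 3))
  expect_equal(estimate_abundance(cov)$insertions, 2)
  cov2 <- flat_coverage(tibble::tibble(family = "TE002", sample = "s1",
                                       value = 2), n_positions = 4)
  expect_equal(estimate_abundance(cov2)$insertions, 2)
  set.seed(14)
  rnd <- tidyr::expand_grid(family = c("a", "b"), sample = c("s1", "s2"),
                            pos = 1:20) %>%
    dplyr::mutate(insertions = runif(dplyr::n(), 0, 5))
  got <- estimate_abundance(rnd)
  want <- aggregate(insertions ~ family + sample, rnd, mean)
  merged <- merge(got, want, by = c("family", "sample"))
  expect_equal(merged$insertions.x, merged$insertions.y, tolerance = 1e-12)
})

test_that("fold changes are anchored and antisymmetric under regime swap", {
  des <- tiny_design(1, 1)
  ab <- abundance_row("TE001", c(Tiny_C1 = 1, Tiny_S1 = 2))
  fc <- fold_changes(ab, des)
  expect_equal(fc$log2fc, 1)
  expect_equal(fc$delta_insertion, 1)
  eq <- fold_changes(abundance_row("TE001", c(Tiny_C1 = 2, Tiny_S1 = 2)), des)
  expect_equal(eq$log2fc, 0)
  expect_equal(eq$delta_insertion, 0)
  # swapping the regimes negates both statistics
  swapped <- des
  swapped$regime <- ifelse(des$regime == "C", "S", "C")
  set.seed(2)
  ab2 <- abundance_row("TE002", c(Tiny_C1 = runif(1, 1, 3),
                                  Tiny_S1 = runif(1, 1, 3)))
  f1 <- fold_changes(ab2, des)
  f2 <- fold_changes(ab2, swapped)
  expect_equal(f1$log2fc, -f2$log2fc, tolerance = 1e-12)
  expect_equal(f1$delta_insertion, -f2$delta_insertion, tolerance = 1e-12)
  # non-positive mean: log2fc NA, delta still defined
  z <- fold_changes(abundance_row("TE003", c(Tiny_C1 = 0, Tiny_S1 = 2)), des)
  expect_true(is.na(z$log2fc))
  expect_equal(z$delta_insertion, 2)
})

test_that("approach #1 recovers planted effects and applies both criteria", {
  des <- study_design("P", 5, 5)
  truth <- sample_reference_families(20, seed = 17)
  truth <- plant_effects(truth, n_s_gt_c = 2, n_c_gt_s = 1, delta = 1.0)
  cov <- generate_coverage_data(truth, des, sigma = 0.1, seed = 17)
  cl <- classify_approach1(cov, des)
  got <- dplyr::left_join(as_tibble(cl), truth[, c("family", "delta")],
                          by = "family")
  expect_true(all(got$label[got$delta > 0] == "S>C"))
  expect_true(all(got$label[got$delta < 0] == "C>S"))

  # identical data in both regimes is NS
  flat <- flat_coverage(
    tidyr::expand_grid(family = "TE001", sample = des$sample) %>%
      dplyr::mutate(value = 2),
    n_positions = 20
  )
  expect_warning(cl_flat <- classify_approach1(flat, des), "residual")
  expect_equal(cl_flat$label, "NS")

  # significant regime term but |delta| <= 0.3 stays NS
  small <- plant_effects(sample_reference_families(10, seed = 18),
                         n_s_gt_c = 1, delta = 0.25)
  cov_small <- generate_coverage_data(small, des, sigma = 0.05, seed = 18)
  cl_small <- classify_approach1(cov_small, des)
  planted <- cl_small[cl_small$family ==
                        small$family[small$delta > 0], ]
  expect_lt(planted$p_raw, 0.01 / nrow(cl_small)) # clearly significant...
  expect_equal(planted$label, "NS")               # ...but fails the size gate
})

test_that("approach #2 finds proportion shifts shared across studies", {
  designs <- dplyr::bind_rows(
    study_design("A", 3, 3),
    study_design("B", 3, 3)
  )
  truth <- sample_reference_families(25, seed = 23)
  truth <- plant_effects(truth, n_s_gt_c = 2, delta = 1.5)
  ab <- dplyr::bind_rows(purrr::map(c("A", "B"), function(st) {
    d <- designs[designs$study == st, ]
    cov <- generate_coverage_data(truth, d, sigma = 0.2,
                                  seed = 100 + match(st, c("A", "B")))
    estimate_abundance(cov, filter_families(cov)) %>%
      dplyr::mutate(study = st)
  }))
  cl2 <- classify_approach2(ab, designs)
  got <- dplyr::left_join(as_tibble(cl2), truth[, c("family", "delta")],
                          by = "family")
  expect_true(all(got$label[got$delta > 0] == "S>C"))
  # proportions are compositional: planting S-shifts cannot create
  # spurious S>C calls among the null families (they shift the other way)
  expect_true(all(got$label[got$delta == 0] != "S>C"))
  # constant proportions everywhere: NS
  const <- tidyr::expand_grid(family = c("x", "y"), sample = designs$sample) %>%
    dplyr::mutate(insertions = ifelse(family == "x", 2, 3),
                  study = substr(sample, 1, 1))
  cl_const <- suppressWarnings(classify_approach2(const, designs))
  expect_true(all(cl_const$label == "NS"))
})

test_that("approach #3 is the strict all-pairwise dominance rule", {
  des <- tiny_design()
  ab <- abundance_row("TE001", c(Tiny_C1 = 2.8, Tiny_C2 = 2.9,
                                 Tiny_S1 = 3.1, Tiny_S2 = 3.2))
  expect_equal(classify_approach3(ab, des)$label, "S>C")
  overlap <- abundance_row("TE001", c(Tiny_C1 = 2.8, Tiny_C2 = 2.9,
                                      Tiny_S1 = 3.1, Tiny_S2 = 2.85))
  expect_equal(classify_approach3(overlap, des)$label, "NS")
  # invariance under replicate permutation and monotone rescaling
  perm <- ab[c(3, 1, 4, 2), ]
  expect_equal(classify_approach3(perm, des)$label, "S>C")
  scaled <- dplyr::mutate(ab, insertions = insertions^3 / 10)
  expect_equal(classify_approach3(scaled, des)$label, "S>C")
})

test_that("approach #3 works per diet in diet-structured designs", {
  des <- tiny_design(1, 1, diets = c("low", "high"))
  ab <- tibble::tibble(
    sample = des$sample,
    insertions = dplyr::case_when(
      des$diet == "low" & des$regime == "S" ~ 3,
      des$diet == "low" ~ 2,
      des$regime == "S" ~ 1,
      TRUE ~ 2
    ),
    family = "TE001"
  )
  cl <- classify_approach3(ab, des)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$label[cl$diet == "low"], "S>C")
  expect_equal(cl$label[cl$diet == "high"], "C>S")
})

test_that("agreement between approaches on strong clean effects", {
  des <- study_design("Q", 4, 4)
  truth <- sample_reference_families(15, seed = 29)
  truth <- plant_effects(truth, n_s_gt_c = 2, n_c_gt_s = 1, delta = 2)
  cov <- generate_coverage_data(truth, des, sigma = 0.05, seed = 29)
  ab <- estimate_abundance(cov)
  l1 <- as_tibble(classify_approach1(cov, des))[, c("family", "label")]
  l3 <- as_tibble(classify_approach3(ab, des))[, c("family", "label")]
  planted <- truth$family[truth$delta != 0]
  m <- dplyr::inner_join(l1, l3, by = "family", suffix = c("_1", "_3"))
  m_planted <- m[m$family %in% planted, ]
  expect_equal(m_planted$label_1, m_planted$label_3)
})

test_that("magnitude comparisons detect planted group differences", {
  set.seed(55)
  mk_cl <- function(study, fc_sgtc, fc_cgts) {
    tibble::tibble(
      study = study,
      family = paste0(study, seq_len(length(fc_sgtc) + length(fc_cgts))),
      label = rep(c("S>C", "C>S"), c(length(fc_sgtc), length(fc_cgts))),
      log2fc = c(fc_sgtc, -abs(fc_cgts)),
      delta_insertion = c(fc_sgtc, -abs(fc_cgts))
    )
  }
  cl <- dplyr::bind_rows(
    mk_cl("big", rnorm(20, 1, 0.1), rnorm(20, 0.3, 0.1)),
    mk_cl("null", rnorm(20, 0.5, 0.1), rnorm(20, 0.5, 0.1))
  )
  res <- magnitude_comparisons(cl)
  p_big <- res$group_fc_tests$p.value[res$group_fc_tests$study == "big"]
  p_null <- res$group_fc_tests$p.value[res$group_fc_tests$study == "null"]
  expect_lt(p_big, 1e-6)
  expect_gt(p_null, 0.05)
  # the study ANOVA separates studies with different |log2fc| scales
  expect_lt(res$study_anova$terms$p.value[1], 0.01)
  expect_equal(nrow(res$study_pairwise), 1)
})

test_that("content models recover a planted total-content regime shift", {
  designs <- dplyr::bind_rows(study_design("A", 3, 3), study_design("B", 3, 3))
  truth <- sample_reference_families(20, seed = 41)
  hier <- dplyr::select(truth, family, subclass, te_class, consensus_length)
  # +10% in every S population, uniformly across families
  ab <- tidyr::expand_grid(truth[, c("family", "copies")],
                           designs[, c("sample", "study", "regime")]) %>%
    dplyr::mutate(insertions = copies * ifelse(regime == "S", 1.1, 1) *
                    exp(rnorm(dplyr::n(), 0, 0.01))) %>%
    dplyr::select(family, sample, study, insertions)
  set.seed(61)
  res <- content_tests(ab, hier, designs)
  expect_equal(
    sum(res$totals$content[res$totals$scope == "total"][1] > 0), 1
  )
  expect_lt(term_p_value(res$models$total, "regime"), 0.001)
  expect_true(all(c("LTR", "non-LTR", "TIR") %in% names(res$models)))
  expect_equal(nrow(res$within_study), 2 * length(unique(res$totals$scope)))
})

test_that("subclass enrichment reduces to the shared Fisher oracle", {
  hier <- tibble::tibble(
    family = paste0("f", 1:8),
    subclass = rep(c("TIR", "LTR"), each = 4),
    te_class = rep(c("DNA", "RNA"), each = 4),
    consensus_length = 1000L
  )
  # S>C group of 4: 3 TIR + 1 LTR against background 4 TIR/4 LTR
  cl <- tibble::tibble(
    family = paste0("f", 1:8),
    label = c("S>C", "S>C", "S>C", "NS", "S>C", "NS", "NS", "NS"),
    log2fc = 1, delta_insertion = 1
  )
  res <- subclass_enrichment(cl, hier)
  tir <- res[res$group == "S>C" & res$type == "TIR", ]
  expect_equal(tir$p.value, oracle_fisher_two_sided(3, 1, 1, 3),
               tolerance = 1e-12)
  # group composition identical to background: p = 1
  bal <- tibble::tibble(
    family = paste0("f", 1:8),
    label = c("S>C", "S>C", "NS", "NS", "S>C", "S>C", "NS", "NS"),
    log2fc = 1, delta_insertion = 1
  )
  res_bal <- subclass_enrichment(bal, hier)
  expect_true(all(res_bal$p.value == 1))
})

test_that("copy-number correction divides counts, defaulting to one copy", {
  counts <- tibble::tibble(family = c("a", "b", "c"), sample = "s1",
                           count = c(100, 50, 10))
  ab <- tibble::tibble(family = c("a", "c"), sample = "s1",
                       insertions = c(4, 0))
  expect_warning(res <- correct_counts_by_copies(counts, ab), "zero-copy")
  expect_equal(res$corrected[res$family == "a"], 25)
  expect_equal(res$corrected[res$family == "b"], 50) # absent -> single copy
  expect_equal(res$corrected[res$family == "c"], 10) # zero -> single copy
  # copies 1 everywhere is the identity
  ab1 <- tibble::tibble(family = c("a", "b", "c"), sample = "s1",
                        insertions = 1)
  expect_equal(correct_counts_by_copies(counts, ab1)$corrected, counts$count)
})

test_that("null-study calibration: approach #1 rarely labels, #3 balanced", {
  des <- study_design("Null", 3, 3)
  truth <- sample_reference_families(40, seed = 77) # all delta = 0
  n_rep <- 30
  labels1 <- integer(0); s3 <- integer(0); c3 <- integer(0)
  for (r in seq_len(n_rep)) {
    cov <- generate_coverage_data(truth, des, sigma = 0.3, n_positions = 30,
                                  seed = 1000 + r)
    ab <- estimate_abundance(cov)
    c3_cl <- classify_approach3(ab, des)
    s3 <- c(s3, sum(c3_cl$label == "S>C"))
    c3 <- c(c3, sum(c3_cl$label == "C>S"))
  }
  # dominance each way has probability 1/C(6,3) = 5%: counts should balance
  diff <- abs(sum(s3) - sum(c3))
  n_trials <- n_rep * nrow(truth)
  expect_lt(diff, 4 * sqrt(2 * 0.05 * n_trials))
})
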