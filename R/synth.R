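# Seeded synthetic-data generator. Emulates the two measurement surfaces the
# pipeline consumes: per-position normalised TE coverage profiles (abundance)
# and genomic insertion tables with per-population frequencies. The generator
# reproduces the statistical structure the analyses assume -- a left-skewed
# site-frequency distribution and a negative coupling between family copy
# number and mean segregating frequency -- and supports planting regime
# effects whose recovery the test suite measures.

#' Sample a synthetic TE family reference set
#'
#' Draws, for each family, a mean segregating frequency from a left-skewed
#' Beta distribution and a copy number (insertions per haploid genome)
#' negatively coupled to that frequency through a Gaussian copula, so that
#' the Spearman correlation between copies and mean frequency hits a
#' configurable target. Young, active families are rare-but-many; old,
#' inactive families are frequent-but-few. The number of insertion sites per
#' family is `round(copies / mean_freq)`, so copy number is consistent with
#' the sum of its site frequencies in expectation.
#'
#' @param n_families Number of TE families (default 179, a typical consensus
#'   library size for Drosophila).
#' @param target_rho Target Spearman correlation between copies and mean
#'   frequency (default -0.5).
#' @param coupling Coupling strength in \[0, 1\] scaling `target_rho`; 0
#'   makes copies and frequencies independent.
#' @param freq_shape1,freq_shape2 Beta shape parameters of the mean site
#'   frequency distribution (default 0.6 and 2.4: left-skewed, most families
#'   rare).
#' @param copies_meanlog,copies_sdlog Log-normal parameters of the copy
#'   number distribution.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A truth tibble with columns `family`, `subclass`, `te_class`,
#'   `consensus_length`, `mean_freq`, `copies`, `n_sites`, `delta` (planted
#'   abundance shift, 0 until set) and `freq_delta` (planted frequency
#'   shift, 0 until set).
#' @export
sample_reference_families <- function(n_families = 179, target_rho = -0.5,
                                      coupling = 1, freq_shape1 = 0.6,
                                      freq_shape2 = 2.4,
                                      copies_meanlog = log(3),
                                      copies_sdlog = 0.9, seed = 1) {
  stopifnot(n_families >= 2, coupling >= 0, coupling <= 1,
            freq_shape1 > 0, freq_shape2 > 0)
  rho <- target_rho * coupling
  if (abs(rho) > 0.98) {
    warn("target correlation near the attainable limit; best effort")
    rho <- sign(rho) * 0.98
  }
  # Gaussian copula: Spearman's rho of the copula is (6/pi) asin(r/2);
  # invert to get the latent normal correlation hitting the target.
  r <- 2 * sin(pi * rho / 6)
  with_substream(seed, "reference_families", {
    z1 <- stats::rnorm(n_families)
    z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n_families)
    mean_freq <- stats::qbeta(stats::pnorm(z1), freq_shape1, freq_shape2)
    mean_freq <- pmin(pmax(mean_freq, 0.005), 0.995)
    copies <- stats::qlnorm(stats::pnorm(z2), copies_meanlog, copies_sdlog)
    subclass <- sample(c("LTR", "non-LTR", "TIR"), n_families, replace = TRUE,
                       prob = c(0.45, 0.35, 0.20))
    tibble(
      family = sprintf("TE%03d", seq_len(n_families)),
      subclass = subclass,
      te_class = ifelse(subclass == "TIR", "DNA", "RNA"),
      consensus_length = sample(1000:9000, n_families, replace = TRUE),
      mean_freq = mean_freq,
      copies = copies,
      n_sites = pmax(1L, as.integer(round(copies / mean_freq))),
      delta = 0,
      freq_delta = 0
    )
  })
}

#' Plant regime effects into a family truth table
#'
#' Marks families as true positives by setting their selected-minus-control
#' abundance shift `delta` (insertions per haploid genome) and/or a latent
#' insertion-frequency shift `freq_delta`. Effects are planted on the
#' families with the largest copy numbers among those that can absorb a
#' negative shift, keeping the assignment deterministic.
#'
#' @param truth Truth tibble from [sample_reference_families()].
#' @param n_s_gt_c Number of families with positive `delta`.
#' @param n_c_gt_s Number of families with negative `delta`.
#' @param delta Magnitude of the planted abundance shift (default 1.0).
#' @param freq_delta Optional frequency shift planted on the same families.
#' @return The truth tibble with `delta`/`freq_delta` filled in.
#' @export
plant_effects <- function(truth, n_s_gt_c = 0, n_c_gt_s = 0, delta = 1.0,
                          freq_delta = 0) {
  stopifnot(n_s_gt_c + n_c_gt_s <= nrow(truth))
  ord <- order(-truth$copies)
  eligible_neg <- ord[truth$copies[ord] > abs(delta) + 0.5]
  if (length(eligible_neg) < n_c_gt_s) {
    abort("not enough high-copy families to plant negative effects")
  }
  idx_neg <- eligible_neg[seq_len(n_c_gt_s)]
  idx_pos <- setdiff(ord, idx_neg)[seq_len(n_s_gt_c)]
  truth$delta[idx_pos] <- abs(delta)
  truth$delta[idx_neg] <- -abs(delta)
  if (freq_delta != 0) {
    truth$freq_delta[c(idx_pos, idx_neg)] <-
      freq_delta * sign(truth$delta[c(idx_pos, idx_neg)])
  }
  truth
}

#' Generate a synthetic per-position coverage profile
#'
#' Emulates the output surface of a coverage-normalised TE abundance
#' estimator: for each family, population and consensus position, the value
#' is `max(0, Normal(copies, sigma))`, where `copies` includes the planted
#' regime shift for selected populations. Gaussian noise truncated at zero
#' models fluctuation of the normalised per-position estimates, not
#' read-level sampling. Each (family, sample) pair draws from its own RNG
#' substream, so adding families or samples does not perturb existing draws.
#'
#' @param truth Truth tibble (see [sample_reference_families()]).
#' @param design Study design tibble (see [study_design()]).
#' @param sigma Standard deviation of the per-position noise (insertions;
#'   default 0.3).
#' @param n_positions Consensus positions per family (default 100).
#' @param seed Integer seed.
#' @return A coverage tibble (`family`, `sample`, `pos`, `insertions`).
#' @export
generate_coverage_data <- function(truth, design, sigma = 0.3,
                                   n_positions = 100, seed = 1) {
  stopifnot(sigma >= 0, n_positions >= 1)
  design <- validate_design(design)
  grid <- tidyr::expand_grid(
    truth[, c("family", "copies", "delta")],
    design[, c("sample", "regime")]
  )
  vals <- purrr::pmap(
    list(grid$family, grid$sample, grid$copies, grid$delta, grid$regime),
    function(fam, smp, cp, dl, rg) {
      mu <- cp + if (rg == "S") dl else 0
      with_substream(seed, paste0("coverage/", fam, "/", smp),
                     pmax(0, stats::rnorm(n_positions, mu, sigma)))
    }
  )
  out <- tibble(
    family = rep(grid$family, each = n_positions),
    sample = rep(grid$sample, each = n_positions),
    pos = rep(seq_len(n_positions), nrow(grid)),
    insertions = unlist(vals)
  )
  validate_coverage(out)
}

#' Generate a synthetic genomic insertion table
#'
#' Places each family's insertion sites uniformly on a synthetic genome of
#' five 20-Mb chromosomes, draws a latent frequency per site from a Beta
#' distribution re-parameterised to the family's mean frequency with a
#' common concentration, then observes each population's frequency as a
#' binomial draw over the `2 * pool_size` chromosomes in the sequencing pool
#' (pool-seq sampling noise). Planted `freq_delta` shifts the latent
#' frequency of selected populations.
#'
#' @param truth Truth tibble.
#' @param design Study design tibble.
#' @param concentration Beta concentration of within-family site frequencies
#'   (default 5; small values = more dispersed sites).
#' @param prop_missing Fraction of (site, population) observations replaced
#'   by `NA` to emulate coverage-dependent detection (default 0).
#' @param perfect_pools If `TRUE`, skip binomial pool sampling and report
#'   the latent frequency exactly (the infinite-pool limit).
#' @param chromosomes Named integer vector of chromosome lengths.
#' @param seed Integer seed.
#' @return A long insertion tibble (`chrom`, `pos`, `family`, `sample`,
#'   `freq`).
#' @export
generate_insertion_data <- function(truth, design, concentration = 5,
                                    prop_missing = 0, perfect_pools = FALSE,
                                    chromosomes = setNames(
                                      rep(2e7L, 5),
                                      paste0("chr", 1:5)
                                    ), seed = 1) {
  stopifnot(concentration > 0, prop_missing >= 0, prop_missing < 1)
  design <- validate_design(design)
  per_family <- purrr::pmap(
    list(truth$family, truth$mean_freq, truth$n_sites, truth$freq_delta),
    function(fam, pbar, ns, fdel) {
      with_substream(seed, paste0("insertions/", fam), {
        chrom <- sample(names(chromosomes), ns, replace = TRUE)
        pos <- integer(ns)
        for (ch in unique(chrom)) {
          sel <- chrom == ch
          pos[sel] <- sample.int(chromosomes[[ch]], sum(sel), replace = FALSE)
        }
        latent <- stats::rbeta(ns, pbar * concentration,
                               (1 - pbar) * concentration)
        latent <- pmin(pmax(latent, 1e-6), 1 - 1e-6)
        rows <- tidyr::expand_grid(
          site = seq_len(ns),
          design[, c("sample", "regime", "pool_size")]
        )
        lat <- latent[rows$site] +
          ifelse(rows$regime == "S", fdel, 0)
        lat <- pmin(pmax(lat, 0), 1)
        freq <- if (perfect_pools) lat else {
          stats::rbinom(nrow(rows), 2L * rows$pool_size, lat) /
            (2 * rows$pool_size)
        }
        if (prop_missing > 0) {
          freq[stats::runif(length(freq)) < prop_missing] <- NA_real_
        }
        tibble(chrom = chrom[rows$site], pos = pos[rows$site], family = fam,
               sample = rows$sample, freq = freq)
      })
    }
  )
  validate_insertions(bind_rows(per_family))
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper tying the generator together: reference families,
#' planted effects, coverage profile and insertion table for one design.
#'
#' @param design Study design tibble.
#' @param n_families,n_s_gt_c,n_c_gt_s,delta See [sample_reference_families()]
#'   and [plant_effects()].
#' @param sigma,n_positions Coverage noise and positions per family.
#' @param seed Integer seed.
#' @param ... Further arguments to [generate_insertion_data()].
#' @return A list with `truth`, `hierarchy`, `coverage` and `insertions`.
#' @export
simulate_study <- function(design, n_families = 100, n_s_gt_c = 0,
                           n_c_gt_s = 0, delta = 1.0, sigma = 0.3,
                           n_positions = 100, seed = 1, ...) {
  truth <- sample_reference_families(n_families, seed = seed)
  truth <- plant_effects(truth, n_s_gt_c, n_c_gt_s, delta = delta)
  hierarchy <- truth %>%
    select("family", "subclass", "te_class", "consensus_length")
  list(
    truth = truth,
    hierarchy = hierarchy,
    coverage = generate_coverage_data(truth, design, sigma = sigma,
                                      n_positions = n_positions, seed = seed),
    insertions = generate_insertion_data(truth, design, seed = seed, ...)
  )
}
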