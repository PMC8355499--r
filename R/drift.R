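# Wright-Fisher drift null for the S>C : C>S imbalance. Replicate
# populations of both breeding regimes evolve independently from shared
# starting frequencies by pure binomial drift (no mutation, no new
# transposition); the empirical neutrality p value asks how often drift
# alone produces at least the observed excess of selection-elevated TE
# families.

#' Wright-Fisher trajectory endpoint(s)
#'
#' Iterates the neutral binomial update `p <- Binomial(2 Ne, p) / (2 Ne)`
#' for `generations` steps. 0 and 1 are absorbing. Vectorised over `p0`.
#'
#' @param p0 Starting frequency (vector allowed), in \[0, 1\].
#' @param ne Effective population size (diploid; 2 Ne chromosomes sampled).
#' @param generations Number of generations (>= 0).
#' @return Final frequencies, same length as `p0`.
#' @export
wf_trajectory <- function(p0, ne, generations) {
  stopifnot(all(p0 >= 0 & p0 <= 1), ne >= 1, generations >= 0)
  p <- p0
  n_chrom <- 2L * as.integer(ne)
  for (g in seq_len(generations)) {
    p <- stats::rbinom(length(p), n_chrom, p) / n_chrom
  }
  p
}

#' Configuration for the drift null simulation
#'
#' Bundles the demography of one study: per-regime effective sizes,
#' generation counts and replicate numbers, plus the fraction of selected
#' flies able to breed at old age (which scales the selected Ne downward,
#' modelling the late-life breeding bottleneck).
#'
#' @param start_freqs Tibble with columns `family`, `p0` and optionally
#'   `n_sites`, giving starting
#'   frequencies, typically family mean frequencies from a reference
#'   population.
#' @param ne_control,ne_selected Effective sizes per regime.
#' @param gen_control,gen_selected Generations per regime (controls breed
#'   early and often, so they usually accumulate more).
#' @param n_rep_control,n_rep_selected Replicate populations per regime.
#' @param breeding_fraction Fraction of selected flies breeding at old age,
#'   in (0, 1]; the selected lineage drifts with
#'   `ceiling(ne_selected * breeding_fraction)`.
#' @param n_sims Number of Monte Carlo simulations (default 5000).
#' @param mode `"family_mean"` (one frequency per family, the default) or
#'   `"per_site"` (evolve `n_sites` independent sites per family and track
#'   their mean).
#' @param seed Master seed; each simulation uses a counter-based substream,
#'   so changing `n_sims` does not reshuffle earlier runs.
#' @return A `drift_config` list.
#' @export
drift_config <- function(start_freqs, ne_control, ne_selected, gen_control,
                         gen_selected, n_rep_control, n_rep_selected,
                         breeding_fraction = 1, n_sims = 5000,
                         mode = c("family_mean", "per_site"), seed = 1) {
  mode <- match.arg(mode)
  stopifnot(
    all(start_freqs$p0 >= 0 & start_freqs$p0 <= 1),
    ne_control >= 1, ne_selected >= 1, gen_control >= 0, gen_selected >= 0,
    n_rep_control >= 1, n_rep_selected >= 1,
    breeding_fraction > 0, breeding_fraction <= 1, n_sims >= 1
  )
  if (mode == "per_site" && is.null(start_freqs$n_sites)) {
    abort("per_site mode needs an n_sites column in start_freqs")
  }
  structure(list(
    start_freqs = as_tibble(start_freqs),
    ne_control = as.integer(ne_control),
    ne_selected_effective = as.integer(ceiling(ne_selected * breeding_fraction)),
    gen_control = as.integer(gen_control),
    gen_selected = as.integer(gen_selected),
    n_rep_control = as.integer(n_rep_control),
    n_rep_selected = as.integer(n_rep_selected),
    breeding_fraction = breeding_fraction,
    n_sims = as.integer(n_sims), mode = mode, seed = seed
  ), class = "drift_config")
}

# Evolve one regime for one simulation: families x replicates matrix of
# final frequencies (per_site mode averages the evolved sites per family).
evolve_regime <- function(config, regime) {
  ne <- if (regime == "S") config$ne_selected_effective else config$ne_control
  gens <- if (regime == "S") config$gen_selected else config$gen_control
  reps <- if (regime == "S") config$n_rep_selected else config$n_rep_control
  p0 <- config$start_freqs$p0
  nf <- length(p0)
  if (config$mode == "family_mean") {
    matrix(wf_trajectory(rep(p0, reps), ne, gens), nrow = nf, ncol = reps)
  } else {
    ns <- config$start_freqs$n_sites
    fam_idx <- rep(seq_len(nf), ns)
    out <- matrix(0, nrow = nf, ncol = reps)
    for (r in seq_len(reps)) {
      finals <- wf_trajectory(rep(p0, ns), ne, gens)
      out[, r] <- as.numeric(tapply(finals, fam_idx, mean))
    }
    out
  }
}

#' Classify one simulated (or observed) replicate-frequency layout
#'
#' Mean-based counts: a family is `S>C` when the mean over selected
#' replicates strictly exceeds the mean over control replicates (exact ties
#' count for neither side). Consistency-based counts use all-pairwise
#' dominance, `min(S) > max(C)`, mirroring the conservative abundance rule.
#'
#' @param s_mat,c_mat Families x replicates matrices of frequencies.
#' @return One-row tibble: `count_sgtc`, `count_cgts`, `consistent_sgtc`,
#'   `consistent_cgts`, `n_ties`.
#' @export
classify_simulation <- function(s_mat, c_mat) {
  ms <- rowMeans(s_mat); mc <- rowMeans(c_mat)
  tibble(
    count_sgtc = sum(ms > mc),
    count_cgts = sum(mc > ms),
    consistent_sgtc = sum(apply(s_mat, 1, min) > apply(c_mat, 1, max)),
    consistent_cgts = sum(apply(c_mat, 1, min) > apply(s_mat, 1, max)),
    n_ties = sum(ms == mc)
  )
}

#' Run the Wright-Fisher drift simulations
#'
#' Evolves every replicate population independently from the shared
#' starting frequencies, `n_sims` times, and classifies each simulation
#' with [classify_simulation()].
#'
#' @param config A [drift_config()].
#' @return A `te_drift_sims` tibble with one row per simulation and the
#'   four counts plus `n_ties`; the config travels as an attribute.
#' @export
simulate_drift <- function(config) {
  stopifnot(inherits(config, "drift_config"))
  res <- purrr::map_dfr(seq_len(config$n_sims), function(s) {
    with_substream(config$seed, paste0("driftsim/", s), {
      s_mat <- evolve_regime(config, "S")
      c_mat <- evolve_regime(config, "C")
      classify_simulation(s_mat, c_mat)
    })
  })
  structure(res, class = c("te_drift_sims", class(res)), config = config)
}

drift_statistic <- function(sgtc, cgts, statistic) {
  denom <- sgtc + cgts
  if (statistic == "proportion") {
    ifelse(denom > 0, sgtc / denom, NA_real_)
  } else {
    ifelse(cgts > 0, sgtc / cgts, NA_real_)
  }
}

#' Empirical neutrality p value for the observed S>C excess
#'
#' Compares the observed proportion of `S>C` among directional families
#' (or the `S>C : C>S` ratio) with its Monte Carlo distribution under pure
#' drift: `p` is the fraction of simulations reaching at least the observed
#' statistic. Simulations with an undefined statistic (no directional
#' family, or a zero denominator for the ratio) are excluded and counted.
#'
#' @param sims A `te_drift_sims` result (or a [drift_config()], which is
#'   simulated first).
#' @param observed_sgtc,observed_cgts Observed counts from an abundance
#'   classification.
#' @param statistic `"proportion"` (default) of S>C among directional
#'   families, or `"ratio"`.
#' @param variant `"mean"` (default) or `"consistent"` simulation counts.
#' @param corrected Use the `(r + 1) / (n + 1)` estimator instead of the
#'   raw fraction (default `FALSE`).
#' @return A `te_drift_result` list: `p.value`, `observed_statistic`,
#'   `sim_statistics`, `n_excluded`, counts and settings; `tidy()` and
#'   `glance()` methods are provided.
#' @export
neutrality_pvalue <- function(sims, observed_sgtc, observed_cgts,
                              statistic = c("proportion", "ratio"),
                              variant = c("mean", "consistent"),
                              corrected = FALSE) {
  statistic <- match.arg(statistic)
  variant <- match.arg(variant)
  if (inherits(sims, "drift_config")) sims <- simulate_drift(sims)
  stopifnot(inherits(sims, "te_drift_sims"))
  cols <- if (variant == "mean") {
    list(sims$count_sgtc, sims$count_cgts)
  } else {
    list(sims$consistent_sgtc, sims$consistent_cgts)
  }
  sim_stat <- drift_statistic(cols[[1]], cols[[2]], statistic)
  obs <- drift_statistic(observed_sgtc, observed_cgts, statistic)
  if (is.na(obs)) abort("observed statistic undefined (no directional family)")
  ok <- !is.na(sim_stat)
  n_excluded <- sum(!ok)
  if (!any(ok)) abort("degenerate configuration (no drift?)")
  r <- sum(sim_stat[ok] >= obs)
  n <- sum(ok)
  p <- if (corrected) (r + 1) / (n + 1) else r / n
  structure(list(
    p.value = p, observed_statistic = obs, sim_statistics = sim_stat,
    n_excluded = n_excluded, n_sims = length(sim_stat),
    observed_sgtc = observed_sgtc, observed_cgts = observed_cgts,
    statistic = statistic, variant = variant, corrected = corrected
  ), class = "te_drift_result")
}

#' @export
print.te_drift_result <- function(x, ...) {
  cat("Drift neutrality test (", x$variant, " counts, ", x$statistic,
      " statistic)\n", sep = "")
  cat("observed:", format(x$observed_statistic, digits = 4),
      " from", x$observed_sgtc, "S>C vs", x$observed_cgts, "C>S\n")
  cat("empirical p =", format(x$p.value, digits = 4), "over",
      x$n_sims - x$n_excluded, "informative simulations (",
      x$n_excluded, "excluded )\n")
  invisible(x)
}

#' Tidy the drift null distribution
#' @param x A `te_drift_result`.
#' @param ... Unused.
#' @return Tibble of per-simulation statistics.
#' @export
tidy.te_drift_result <- function(x, ...) {
  tibble(sim = seq_along(x$sim_statistics), statistic = x$sim_statistics)
}

#' One-row summary of a drift neutrality test
#' @param x A `te_drift_result`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.te_drift_result <- function(x, ...) {
  tibble(
    p.value = x$p.value, observed_statistic = x$observed_statistic,
    mean_sim_statistic = mean(x$sim_statistics, na.rm = TRUE),
    n_sims = x$n_sims, n_excluded = x$n_excluded,
    statistic = x$statistic, variant = x$variant
  )
}
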