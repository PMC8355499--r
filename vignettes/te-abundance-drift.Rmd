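---
title: "Methods: TE abundance, insertion frequency, and the drift null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TE abundance, insertion frequency, and the drift null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind `televolve`, the
parameters that matter and why their defaults were chosen, what the
synthetic-data generator does and does not emulate, and the numerical
conventions a careful user should know about.

## The measurement surfaces

Two inputs drive everything.

*Coverage profiles* give, for each TE family, population sample and
1-based consensus position, a coverage-normalised estimate of insertions
per haploid genome. Such estimates come from mapping pooled reads to a TE
consensus library and dividing by single-copy-gene depth; `televolve`
consumes that output surface and never touches reads. Averaging over
consensus positions yields one abundance value per family and population
(`estimate_abundance()`).

*Insertion tables* give exact genomic positions of individual TE
insertions and their frequency in each sequenced pool, as produced by
split-read/discordant-pair callers on pool-seq data. Detection is
coverage-dependent, so a site may be missing (`NA`) in some populations;
sites are then excluded from tests requiring those populations, and the
per-site Bonferroni divisor counts only sites actually tested.

All coordinates, everywhere, are 1-based inclusive
(`TE_COORDINATE_SYSTEM`); file dialects are UTF-8 TSV with the literal
token `NA` for missing values.

## Family retention filter

A family enters the analysis only if, averaging the per-position values
over all populations of the study, at least 80% of its consensus
positions reach 0.5 insertions. Both boundaries are inclusive: exactly
80% of positions, or a position average of exactly 0.5, counts. The
filter removes families that are absent or too patchily covered for the
per-position ANOVA to be meaningful; in the synthetic reference with
log-normal copy numbers (median 3), it typically removes the few
families with < 0.5 copies, mirroring the small excluded fraction seen in
real libraries of ~179 consensus sequences.

## Three abundance classifications

**Approach 1 (per study, least conservative).** For each retained family
a sequential (type I) ANOVA is fitted to the per-position values:
`insertions ~ Regime + Population[Regime]`, i.e. replicate populations
nested within regime, or `Regime + Diet + Regime×Diet` for designs with a
larval-diet treatment. Every term is tested against the residual mean
square, matching the classical `aov` idiom. Treating positions within a
population as independent observations is deliberate pseudoreplication:
the per-position values are fluctuations of one underlying copy-number
estimate, so p-values are anticonservative in absolute terms. Two gates
compensate: Bonferroni correction across the retained families at
α = 0.01, and an effect-size requirement |δ| > 0.3 insertions (on
average, at least ~30% of chromosomes in the pools differ by one
insertion). δ and log₂FC are computed from regime means of the
per-population abundances; for diet designs they pool across diets so
each family gets one label per study.

**Approach 2 (joint, compositional).** Families retained in *every*
study are re-expressed as the arcsine-square-root transformed share of
the population's total TE content, and one model per family is fitted
across studies: `Study + Regime + Study×Regime`, regime p-values BH
adjusted at FDR 0.05. Because shares sum to one, a genuine expansion of
some families necessarily depresses the shares of the rest; directions
must be read compositionally (the test suite checks exactly this
property rather than pretending null families stay `NS`).

**Approach 3 (consistency, most conservative).** A family is labelled
only under strict all-pairwise dominance: min over selected populations
greater than max over controls (or vice versa), computed within diets for
diet-structured designs. "Consistent" is read as all-pairwise dominance
rather than some replicate pairing because replicate counts differ
between regimes in general, making pairing ill-defined. The rule uses no
test statistic, so labels are invariant to any common monotone rescaling
and to replicate order.

## Frequency analytics

The mean frequency of a family's detected insertions is the standard
proxy for its evolutionary age and recent activity: young, active
families segregate at low frequencies across many sites. The generator
couples copy number and mean frequency negatively (target Spearman
ρ = −0.5 through a Gaussian copula), and
`abundance_frequency_correlation()` recovers that coupling through the
full analysis path.

Per-site differentiation fits `asin√(freq) ~ Regime` (plus diet terms
where applicable) per insertion site, with a Bonferroni threshold
α = 0.05 divided by the number of sites actually tested. Per-family
differentiation pools all site × population transformed frequencies of a
family as independent observations of one model (`Regime +
Population[Regime]`), BH-adjusted across families — again the field's
ANOVA idiom, with no site random effect; sites are equally weighted.

Gene annotation classifies sites as `inside` (start ≤ pos ≤ end),
`upstream`/`downstream` within 1000 bp of the nearest gene edge
(inclusive at exactly 1000; strand decides which side is upstream), else
`intergenic`. The window is measured from the annotated gene start/end
because UTR coordinates are not modelled. Among equidistant genes the
lexicographically smallest identifier wins, making annotation
deterministic; the test suite verifies exact strand symmetry under
coordinate reflection.

## The Wright–Fisher drift null

Each family's starting frequency p₀ evolves independently per replicate
population as `p ← Binomial(2Nₑ, p) / 2Nₑ` for the regime's number of
generations; 0 and 1 are absorbing; there is no mutation and no new
transposition — the null is drift-only by construction. The late-life
breeding bottleneck enters through `breeding_fraction`: the selected
lineage drifts with `⌈Nₑ · breeding_fraction⌉`.

Two classification variants are reported side by side, because the
observed counts come from either approach 1 (mean-based) or approach 3
(consistency): a family is `S>C` when the mean over selected replicates
strictly exceeds the control mean (exact ties count for neither side;
at plausible Nₑ they are rare and reported), or, in the consistency
variant, under all-pairwise dominance. `family_mean` mode evolves one
frequency per family (the mean-frequency summary that also seeds the
simulation); `per_site` mode evolves `n_sites` independent sites and
tracks their mean — with one site per family the two are
distributionally identical, which the tests check by KS.

The empirical neutrality p-value is the raw fraction of simulations whose
`S>C/(S>C + C>S)` proportion (ties excluded from the denominator) reaches
the observed one; a `(r+1)/(n+1)` estimator is available behind
`corrected = TRUE`. Simulations with no directional family are excluded
and counted.

Two calibration properties pin the implementation down. Under a fully
symmetric demography the two directional counts are exchangeable, and the
neutrality p-value of null "observations" is uniform. Note one subtlety:
within a single simulation the two counts nearly sum to the number of
families and are therefore strongly negatively correlated, so the
exchangeability check compares counts from independent halves of the
simulations — a two-sample KS between paired, anticorrelated samples
would reject spuriously. Under an asymmetric demography in which control
lineages accumulate more generations (they breed early and often, while
selected lines wait for late-life reproduction), left-skewed starting
frequencies drift toward loss in the long-history regime and the chance
proportion of `S>C` calls grows monotonically with control generations;
at the same time the consistency variant keeps producing more
consistently-C than consistently-S families. The acceptance suite
asserts both on a fixed configuration (Nₑ = 200, selected bottleneck
fraction 0.25, selected lineage at 100 generations, controls swept
100→300, 4 replicates per regime, 100 families, 600 simulations per
point) chosen to reflect a long-term selection experiment.

RNG discipline: every simulation draws from its own substream derived
from the master seed by a rolling polynomial hash of a counter label, so
increasing `n_sims` extends a run without reshuffling earlier
simulations, and results are reproducible bit-for-bit under a seed.

## Cross-study sharing

The probability of an observed m-way overlap among the studies'
significant family sets is computed exactly under independent uniform
sampling of each set from the common background (families retained in
every study — a family unobservable in a study cannot be called there).
The distribution of the running intersection follows a chain of
hypergeometric mixtures: given the first j−1 sets intersect in t
elements, set j overlaps that intersection as Hypergeometric(n, t, sⱼ).
All sets are treated as random; none is conditioned on as fixed. The
test suite verifies the full distribution against an independent
multinomial cell-count enumeration for every background n ≤ 12 and two
or three sets, and the pmf sums to one within 1e-9 in every
configuration used. The overlap significance flag is 0.05 unadjusted.

## Statistical primitives and conventions

The primitives wrap base R behind a uniform tibble interface, and each is
oracle-tested: Welch t (closed form; zero-variance edge cases resolved
explicitly: equal means → t = 0, p = 1; unequal → ±∞, p = 0, flagged),
Spearman/Pearson correlation (average ranks, t approximation), Fisher's
exact 2×2 (two-sided by the "probability at most observed" convention,
not doubling; a zero margin yields p = 1 with an undefined odds ratio),
Pearson χ² without continuity correction, Bonferroni thresholds (α/n),
BH adjustment (NAs propagate and are excluded from n), and pairwise
Welch tests with Holm adjustment. Post-hoc contrasts after the
between-study ANOVA use pairwise Welch + Holm rather than a
studentized-range procedure; conclusions from them are qualitative.
F/t/χ² tail probabilities come from R's distribution functions, accurate
far beyond the thresholds used here.

Degenerate fits are never silently inflated: zero residual variation
yields `NA` F statistics with a warning (suppressed, per site, in the
per-site scan where invariant fixed sites are legitimate and common).

## What the generator emulates — and what it does not

Emulated: per-position coverage noise as truncated Gaussian
(σ = 0.3 insertions by default) around the family's true copy number —
a model of the *output* of a normalised coverage estimator, not of
reads; left-skewed mean site frequencies (Beta(0.6, 2.4): most families
rare, a tail of old fixed families); negative copy–frequency coupling
(Gaussian copula, Spearman target −0.5, attained within ±0.15 at 200
families); site counts `n_sites ≈ copies / mean_freq`, keeping copy
number consistent with the sum of site frequencies; within-family site
dispersion Beta with concentration 5 (a free parameter — no published
dispersion exists to copy); binomial pool sampling over `2 × pool_size`
chromosomes; uniform site placement on five 20-Mb chromosomes.

Not emulated: read-level sampling and mapping artefacts, piRNA-cluster
and heterochromatin clustering of insertions, linkage between sites,
coverage-dependent detection bias beyond i.i.d. missingness, and any
correlation between a family's subclass and its dynamics. Passing tests
therefore demonstrate correctness of the *analysis machinery* under the
assumed statistical structure, not robustness to every artefact of real
pool-seq data.

Default study layouts (`default_study_designs()`) emulate four published
late-breeding selection experiments qualitatively: two long-term studies
(5 and 4 replicates per regime), a short-term study (3 per regime), and
a diet-structured study (3 diets × 2 replicates per regime), with pool
sizes of 100–250 females, control lineages at 2–4× the selected line's
elapsed generations and breeding fractions of 0.25–0.5. Replicate
counts, Nₑ and generation numbers are package choices on the right order
of magnitude for laboratory *Drosophila*, made once; they are inputs to
the drift null, not fitted quantities.

## Problem sizes

The test and acceptance workloads are sized for quick, repeatable runs:
planted-recovery studies use 100 families × 10 populations per regime ×
100 positions (σ = 0.3; 20 families at δ = +1, 10 at −1); null
calibrations use 2,000 simulations plus 200 held-out observations at
Nₑ = 100, 40 generations, 3 replicates per regime; the asymmetry sweep
uses 600 simulations per control-generation point; Wright–Fisher moments
use 10,000 trajectories. Enumeration oracles sweep all 2×2 tables with
N ≤ 20 and all intersection configurations with background ≤ 12.

## Known limitations

Approach 1 inherits the pseudoreplication of the per-position idiom; its
p-values rank families rather than carry literal error rates (hence the
Bonferroni + effect-size double gate). Approach 2's compositional
denominators couple families. The drift null fixes starting frequencies
at the reference means instead of modelling their uncertainty, and
`family_mean` mode treats a family's abundance as one locus — `per_site`
mode relaxes this but still assumes free recombination between sites.
The annotation rule knows gene bodies only, not UTRs or regulatory
context.
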