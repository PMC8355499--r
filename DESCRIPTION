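Package: televolve
Title: Transposable Element Abundance, Insertion Frequency, and Drift
    Null Analysis for Experimentally Evolved Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing transposable element (TE) landscapes in
    pool-sequenced experimental evolution studies, motivated by selection
    experiments for longevity through late-life reproduction in Drosophila.
    Provides readers for per-position normalised TE coverage profiles and
    genomic insertion-frequency tables, three complementary approaches for
    classifying TE families as differentially abundant between breeding
    regimes, family-level segregating-frequency analytics, an exact
    multi-set intersection test for cross-study sharing, a Wright-Fisher
    drift simulator with an empirical neutrality test for the observed
    excess of selection-elevated families, and a seeded synthetic-data
    generator that emulates the statistical structure of the real inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
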