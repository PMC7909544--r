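Package: marshfun
Title: Functional-Gene Array and Community Analysis for Degraded Wetland Soils
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for functional gene microarray (GeoChip-style)
    and amplicon community data from wetland soil surveys. Provides
    signal-to-noise filtering and relative-abundance normalization of
    probe-level array signals, gene-family aggregation, the weighted
    response-ratio effect-size meta-analysis with confidence-interval
    significance calls and functional-category shift summaries,
    first-principles community statistics (rarefaction, alpha diversity,
    Bray-Curtis dissimilarity, non-metric multidimensional scaling, Mantel,
    ANOSIM, PERMANOVA), canonical correspondence analysis with
    variance-inflation screening, permutation forward selection and two-group
    variation partitioning, and synthetic-data generators that emulate a
    multi-site two-marsh degradation study with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
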