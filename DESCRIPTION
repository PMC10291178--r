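Package: reliotu
Title: Replicate Reliability and Low-Abundance OTU Filtering for 16S
    Count Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools to assess how low-abundance OTU filtering affects the
    reliability of 16S rRNA amplicon surveys sequenced in replicate.
    Implements six filtering strategies scoped to the whole dataset,
    the individual sample, or the triplicate; a replicate-agreement
    (reliability) statistic; per-OTU coefficients of variation binned by
    abundance; alpha-diversity estimators (observed richness,
    bias-corrected Chao1, Shannon, inverse Simpson); Bray-Curtis
    beta-diversity with principal-coordinates ordination and a seeded
    permutation PERMANOVA; and a synthetic triplicate community
    generator with known ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
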