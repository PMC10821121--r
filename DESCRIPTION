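Package: fmtengraft
Title: Donor Bacteria Engraftment Analysis for Fecal Microbiota
    Transplants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies engraftment of donor bacteria in recipients of
    fecal microbiota transplants (FMT) profiled by 16S rRNA amplicon
    sequencing. Given an ASV count table, sample metadata and an optional
    phylogeny, the package assembles donor/pre-FMT/post-FMT triads,
    computes per-recipient donor-ASV engraftment rates, partitions each
    post-FMT microbiome into donor-derived, recipient-derived,
    always-shared and environmental fractions, summarises which taxa
    engraft most often, and relates donor-recipient community overlap
    (weighted UniFrac similarity) to donor-derived abundance. Includes
    the supporting alpha-diversity estimators (Chao1, Shannon,
    Gini-Simpson), beta-diversity distances (Jaccard, Bray-Curtis,
    Aitchison, weighted UniFrac), rarefaction, and a synthetic FMT cohort
    generator with ground-truth labels for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    withr,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
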