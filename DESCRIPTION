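Package: msea
Title: Metabolite Set Enrichment Analysis for Untargeted Metabolomics
    Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pathway-based interpretation of untargeted metabolomics
    (next-generation metabolic screening) data for single-patient
    diagnostics. Detects features that deviate between one patient and
    its batch controls (robust Z statistic, Benjamini-Hochberg
    correction), annotates features to metabolites by adduct-corrected
    neutral mass within a ppm tolerance, maps annotations to pathway
    databases, scores per-pathway over-representation of aberrant
    features with a one-sided Fisher exact test (Bonferroni-Holm
    corrected), clusters redundant enriched pathways driven by the same
    aberrant metabolites, ranks known biomarker metabolites at feature,
    pathway and cluster level with permutation significance, and
    extracts putative novel biomarkers and cohort-shared confounder
    pathways. Includes a fully deterministic synthetic-cohort generator
    so that every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
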