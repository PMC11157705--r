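Package: herbprox
Title: Network Proximity Measures for Herb-Disease Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts associations between multi-compound natural herbs and
    diseases from their molecular footprints in the human protein interactome.
    Association tables (disease-gene, herb-compound, compound-gene) are
    evidence-filtered, joined into disease gene sets and herb gene sets with
    per-gene compound-multiplicity weights, and scored with three network
    proximity measures: average shortest path length (ASP), average closest
    path length (ACP), and the weighted average closest path length (WACP),
    which divides each herb gene's closest distance to the disease module by
    the number of compounds in the herb that target it. Includes ranking
    evaluation against a gold standard (AUROC, AUPRC, per-herb and per-disease
    AUROC, correlation diagnostics, FPR-anchored thresholds), rule-based
    discovery of novel herb-disease candidates, and a seeded synthetic-data
    generator with planted proximity-plus-multiplicity signal for end-to-end
    benchmarking without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
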