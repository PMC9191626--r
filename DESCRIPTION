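Package: inflammaging
Title: Inflamm-Aging Scoring, Expression-Based Causal Inference, and
    Differential Network Analysis for Atherosclerosis Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the inflamm-aging hypothesis in atherosclerosis
    from gene-expression cohorts: multi-batch synthetic cohort simulation with
    a planted age -> inflammation -> disease causal chain, an eight-step
    preprocessing pipeline (zero filtering, outlier-aware log transform,
    reference z-scoring, SVD batch-component removal), interaction-feature
    predictors with ReliefF ranking and cosine kNN cross-validation, a
    k-nearest-neighbour inflamm-aging score with age adjustment, an
    expression-based Mendelian-randomization filter cascade for aging ->
    disease marker pairs, score-conditioned differential co-expression
    networks with scale-free checks and shortest-path extraction,
    Metropolis-Hastings sensitivity analysis, hypergeometric shortest-path
    enrichment against GMT gene sets, and permutation-tested betweenness
    network markers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
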