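test_that("the logistic age transform hits its closed-form anchors", {
  expect_identical(transform_age(50), 0.5)
  expect_equal(transform_age(0), 1 / (1 + exp(1)))
  expect_equal(transform_age(1e6), 1, tolerance = 1e-12)
  expect_true(all(diff(transform_age(seq(0, 100, by = 5))) > 0))
  expect_error(transform_age(-1))
})

test_that("relevance is the Pearson correlation of the gene product with the phenotype", {
  g <- c(1, 2, 3, 4)
  expect_equal(relevance(g, g, g), cor(g^2, g))
  expect_equal(relevance(g, g, g), 0.9843, tolerance = 1e-4)
  expect_warning(r0 <- relevance(g, g, rep(1, 4)), "zero-variance")
  expect_equal(r0, 0)
  expect_equal(relevance(c(1, 2, 3, 4), c(1, 1, 1, 1), c(1, 2, 3, 4)), 1)
})

test_that("interaction transform keeps floor(log2(n+1)) partners and matches the oracle", {
  set.seed(21)
  for (n_genes in c(4, 7, 10)) {
    X <- matrix(rnorm(n_genes * 12), n_genes,
                dimnames = list(paste0("g", seq_len(n_genes)), paste0("s", 1:12)))
    ph <- rnorm(12)
    got <- interaction_transform(X, ph)
    expect_equal(got, oracle_interaction(X, ph), tolerance = 1e-10,
                 ignore_attr = TRUE)
    k_expect <- floor(log2(n_genes - 1 + 1))
    expect_true(all(vapply(attr(got, "partners"), nrow, integer(1)) == k_expect))
  }
  ## n = 7 genes: each anchor has 6 partners available -> floor(log2(7)) = 2;
  ## with 8 genes (7 partners) exactly 3 partners are kept
  X8 <- matrix(rnorm(8 * 10), 8, dimnames = list(paste0("g", 1:8), paste0("s", 1:10)))
  got8 <- interaction_transform(X8, rnorm(10))
  expect_true(all(vapply(attr(got8, "partners"), nrow, integer(1)) == 3L))
})

test_that("an anchor without partners yields an all-zero feature with a warning", {
  X <- matrix(rnorm(8), 1, dimnames = list("g1", paste0("s", 1:8)))
  expect_warning(out <- interaction_transform(X, rnorm(8)), "no partners")
  expect_equal(unname(out["g1", ]), rep(0, 8))
})

test_that("ReliefF ranks a class-separating feature first and breaks ties by input order", {
  set.seed(31)
  n <- 60
  labels <- rep(c(0, 1), each = n / 2)
  F <- cbind(sep = labels + rnorm(n, 0, 0.05),
             n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  expect_equal(relieff_rank(F, labels)[1], "sep")
  ## a duplicated feature gets adjacent ranks in input order
  F2 <- cbind(F, sep_copy = F[, "sep"])
  rk <- relieff_rank(F2, labels)
  i <- match(c("sep", "sep_copy"), rk)
  expect_equal(diff(i), 1L)
  expect_error(relieff_rank(F, rep(1, n)), "both classes")
})

test_that("cosine kNN separates well-separated classes and is at chance under permuted labels", {
  set.seed(41)
  n <- 200; d <- 5
  labels <- rep(c(0, 1), each = n / 2)
  F <- matrix(rnorm(n * d, 0, 0.1), n, d) +
    outer(labels, rep(1, d)) + outer(1 - labels, c(1, 0, 0, 0, -1))
  colnames(F) <- paste0("f", 1:d)
  fit <- fit_knn_predictor(F, labels, predictor_config(candidate_feature_counts = c(2, 5)))
  expect_gte(max(fit$cv_curve), 0.95)
  perm <- sample(labels)
  fitp <- fit_knn_predictor(F, perm, predictor_config(candidate_feature_counts = c(2, 5)))
  expect_gte(max(fitp$cv_curve), 0.4)
  expect_lte(min(fitp$cv_curve), 0.6)
  ## a single candidate count is always chosen
  fit1 <- fit_knn_predictor(F, labels, predictor_config(candidate_feature_counts = 3))
  expect_equal(fit1$chosen_count, 3L)
})

test_that("kNN prediction is deterministic with contract tie-breaks", {
  train <- rbind(c(1, 0), c(0, 1), c(1, 1))
  labels <- c(0, 1, 1)
  ## k = 3 over all points; vote 2:1 for class 1
  expect_equal(knn_cosine_predict(train, labels, rbind(c(1, 1)), k = 3), 1)
  ## k = 2 tie between class 0 and 1 -> smaller class (0) wins
  expect_equal(knn_cosine_predict(rbind(c(1, 0), c(0, 1)), c(0, 1),
                                  rbind(c(1, 1)), k = 2), 0)
  expect_error(knn_cosine_predict(train, labels, rbind(c(1, 1)), k = 9), "exceeds")
})

test_that("the improved model recovers planted inflammatory markers", {
  co <- planted_cohort()
  sets <- truth_gene_sets(co$raw, n_decoys = 0)
  ## candidate inflammatory set = planted mediators plus unrelated genes
  inflam_cand <- c(sets$SYNTH_INFLAMMATORY_MEDIATORS, co$null[1:20])
  mm <- build_improved_model(co$pp, inflam_cand,
                             aging_markers = c(co$aging, co$null[21:40]),
                             candidate_disease_markers = c(co$disease, co$null[41:60]),
                             config = predictor_config(seed = 2L))
  expect_gte(mean(sets$SYNTH_INFLAMMATORY_MEDIATORS %in% mm$inflammatory_markers),
             0.6)
  ## final sets are disjoint from the inflammatory candidates where required
  expect_length(intersect(mm$aging_markers, inflam_cand), 0)
  ## a disjoint inflammatory set leaves aging candidates untouched by step 1
  expect_error(build_improved_model(co$pp, character(0), co$aging, co$disease),
               "empty inflammatory gene set")
})

test_that("marker selection is reproducible bit-for-bit from (data, seed, config)", {
  co <- planted_cohort()
  cfg <- predictor_config(seed = 9L, candidate_feature_counts = c(10, 20))
  small <- subset_study(co$pp, genes = c(co$aging[1:10], co$inflammation[1:10],
                                         co$null[1:20]))
  a <- select_markers(small, "disease", cfg)
  b <- select_markers(small, "disease", cfg)
  expect_identical(a$markers, b$markers)
  expect_identical(a$model$cv_curve, b$model$cv_curve)
})
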