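# Shared fixtures built in code. Expensive artifacts are computed once per
# test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# default planted cohort, preprocessed, with convenience role lists
planted_cohort <- function() {
  cached("planted", {
    study <- generate_cohort(cohort_config(seed = 42L))
    pp <- preprocess(study)
    tr <- pp$truth
    genes <- rownames(pp$expression)
    list(
      raw = study,
      pp = pp,
      aging = intersect(tr$gene_id[tr$role == "aging"], genes),
      inflammation = intersect(tr$gene_id[tr$role == "inflammation"], genes),
      disease = intersect(tr$gene_id[tr$role == "disease"], genes),
      null = intersect(tr$gene_id[tr$role == "null"], genes)
    )
  })
}

planted_scores <- function() {
  cached("planted_scores", {
    co <- planted_cohort()
    score_study(co$pp, co$inflammation, "aging")
  })
}

# transcriptome-scale cohort (1000 genes) for the enrichment demonstration:
# hypergeometric path enrichment needs a universe much larger than the
# planted sets to be meaningful
planted_big <- function() {
  cached("planted_big", {
    study <- generate_cohort(cohort_config(n_genes = 1000, seed = 42L))
    pp <- preprocess(study)
    tr <- pp$truth
    genes <- rownames(pp$expression)
    inflammation <- intersect(tr$gene_id[tr$role == "inflammation"], genes)
    list(raw = study, pp = pp,
         aging = intersect(tr$gene_id[tr$role == "aging"], genes),
         inflammation = inflammation,
         score = score_study(pp, inflammation, "aging"))
  })
}

# a tiny deterministic study for container-level tests
tiny_study <- function(n_genes = 3, n_samples = 4, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n_genes * n_samples, 8), n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  new_expression_study(X, age = seq(30, by = 10, length.out = n_samples),
                       disease = rep_len(c(0, 1), n_samples),
                       batch = rep("b1", n_samples),
                       split = rep("train", n_samples))
}
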