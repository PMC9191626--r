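# brute-force oracle: per-pair group statistics computed one pair at a time
oracle_edge_stats <- function(X, score, disease) {
  genes <- rownames(X)
  pairs <- t(combn(genes, 2))
  do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    one <- function(idx) {
      c(corr = cor(X[a, idx], X[b, idx]),
        pcorr = partial_corr(X[a, idx], X[b, idx], score[idx]))
    }
    d <- one(which(disease == 1)); h <- one(which(disease == 0))
    data.frame(gene_a = a, gene_b = b, corr_dis = d["corr"], corr_ctl = h["corr"],
               pcorr_dis = d["pcorr"], pcorr_ctl = h["pcorr"])
  }))
}

test_that("groupwise edge statistics match a per-pair brute-force oracle", {
  set.seed(51)
  X <- matrix(rnorm(5 * 40), 5, dimnames = list(paste0("g", 1:5), paste0("s", 1:40)))
  score <- rnorm(40)
  disease <- rep(c(0, 1), each = 20)
  got <- groupwise_edge_statistics(X, score, disease)
  ref <- oracle_edge_stats(X, score, disease)
  key <- function(d) paste(pmin(d$gene_a, d$gene_b), pmax(d$gene_a, d$gene_b))
  ref <- ref[match(key(got), key(ref)), ]
  for (col in c("corr_dis", "corr_ctl", "pcorr_dis", "pcorr_ctl"))
    expect_equal(got[[col]], unname(ref[[col]]), tolerance = 1e-10)
  ## symmetry in gene order: one row per unordered pair
  expect_equal(nrow(got), choose(5, 2))
  expect_error(groupwise_edge_statistics(X, score, rep(0, 40)), ">= 4 samples")
})

test_that("the sign-flip edge rule is applied as specified", {
  base <- data.frame(gene_a = "a", gene_b = "b",
                     corr_dis = 0.5, corr_ctl = 0.2,
                     pcorr_dis = 0.1, pcorr_ctl = 0.3,
                     dcorr = 0.3, dpcorr = -0.2,
                     p_corr = 0.001, p_pcorr = 0.001,
                     fdr_corr = 0.01, fdr_pcorr = 0.01,
                     p_dcorr = 0.01, p_dpcorr = 0.01,
                     fdr_dcorr = 0.05, fdr_dpcorr = 0.05)
  net <- build_differential_network(base)
  expect_equal(nrow(net$edges), 1)
  ## both differences positive -> dropped regardless of significance
  same <- transform(base, dpcorr = 0.2)
  expect_equal(nrow(build_differential_network(same)$edges), 0)
  ## sign zero never passes
  zero <- transform(base, dpcorr = 0)
  expect_equal(nrow(build_differential_network(zero)$edges), 0)
  ## coefficient mode requires significant coefficients
  weak <- transform(base, p_corr = 0.5, fdr_corr = 0.9)
  expect_equal(nrow(build_differential_network(weak)$edges), 0)
  ## difference mode keys on the difference tests instead
  weakd <- transform(base, p_dcorr = 0.5)
  expect_equal(nrow(build_differential_network(weakd, edge_test = "difference")$edges), 0)
  expect_equal(nrow(build_differential_network(weakd, edge_test = "coefficient")$edges), 1)
})

test_that("score-mediated structure forms edges far above the null-pair rate", {
  co <- planted_cohort()
  sc <- planted_scores()
  trn <- co$pp$split == "train"
  genes <- c(co$aging, co$inflammation, sample(co$null, 40))
  es <- groupwise_edge_statistics(co$pp$expression[genes, trn], sc[trn],
                                  co$pp$disease[trn])
  net <- build_differential_network(es)
  role_of <- function(g) ifelse(g %in% co$aging, "aging",
                                ifelse(g %in% co$inflammation, "inf", "null"))
  cls <- paste(role_of(net$edges$gene_a), role_of(net$edges$gene_b))
  planted_pairs <- length(co$aging) * length(co$inflammation)
  null_pairs <- choose(40, 2)
  rate_planted <- sum(cls %in% c("aging inf", "inf aging")) / planted_pairs
  rate_null <- sum(cls == "null null") / null_pairs
  expect_gte(rate_planted, 3 * max(rate_null, 1 / null_pairs))
  ## degree table sums to twice the edge count
  expect_equal(sum(net$degree), 2 * nrow(net$edges))
})

test_that("scale-free check behaves on power-law, regular, and star graphs", {
  set.seed(61)
  g <- igraph::sample_pa(1000, m = 2, directed = FALSE)
  res <- scale_free_check(igraph::degree(g))
  expect_lt(res$r, -0.6)
  expect_lt(res$p_value, 0.01)
  ring <- igraph::make_ring(50)
  expect_error(scale_free_check(igraph::degree(ring)), "distinct degrees")
  star <- igraph::make_star(51, mode = "undirected")
  expect_error(scale_free_check(igraph::degree(star)), "distinct degrees")
})

test_that("cross-cohort validation gives tiny p for identical nets, uniform for random", {
  mk_net <- function(edges, nodes) {
    df <- data.frame(gene_a = edges[, 1], gene_b = edges[, 2])
    g <- igraph::graph_from_data_frame(df, directed = FALSE,
                                       vertices = data.frame(name = nodes))
    list(edges = df, graph = g, degree = igraph::degree(g))
  }
  nodes <- paste0("g", 1:100)
  set.seed(71)
  same <- t(replicate(100, sample(nodes, 2)))
  key <- paste(pmin(same[, 1], same[, 2]), pmax(same[, 1], same[, 2]))
  same <- same[!duplicated(key), , drop = FALSE]
  net <- mk_net(same, nodes)
  v <- cross_cohort_validation(net, net)
  expect_lt(v$p_value, 1e-20)
  ## independent random edge sets: Fisher's exact p is discrete and
  ## conservative, so assert calibration of the rejection rate rather than
  ## exact uniformity
  p <- replicate(300, {
    e1 <- t(replicate(40, sample(nodes, 2)))
    e2 <- t(replicate(40, sample(nodes, 2)))
    cross_cohort_validation(mk_net(e1, nodes), mk_net(e2, nodes))$p_value
  })
  expect_lte(mean(p < 0.05), 0.07)
  expect_gt(mean(p), 0.4)
  empty <- mk_net(matrix(character(0), 0, 2), nodes)
  expect_error(cross_cohort_validation(net, empty), "empty")
})

test_that("shortest paths use unit weights with lexicographic tie-breaks", {
  mk_net <- function(edges, nodes) {
    df <- data.frame(gene_a = edges[, 1], gene_b = edges[, 2])
    g <- igraph::graph_from_data_frame(df, directed = FALSE,
                                       vertices = data.frame(name = nodes))
    list(edges = df, graph = g, degree = igraph::degree(g))
  }
  ## path graph a - b - c
  net <- mk_net(rbind(c("a", "b"), c("b", "c")), c("a", "b", "c"))
  got <- shortest_paths_for_pairs(net, data.frame(aging_marker = "a",
                                                  disease_marker = "c"))
  expect_equal(got$paths[[1]], c("a", "b", "c"))
  expect_equal(got$lengths, 2L)
  ## adjacent pair -> the direct edge
  got2 <- shortest_paths_for_pairs(net, data.frame(aging_marker = "a",
                                                   disease_marker = "b"))
  expect_equal(got2$lengths, 1L)
  ## two equal-length routes: a-b-d and a-c-d -> lexicographically smallest
  net3 <- mk_net(rbind(c("a", "b"), c("b", "d"), c("a", "c"), c("c", "d")),
                 c("a", "b", "c", "d"))
  got3 <- shortest_paths_for_pairs(net3, data.frame(aging_marker = "a",
                                                    disease_marker = "d"))
  expect_equal(got3$paths[[1]], c("a", "b", "d"))
  ## unreachable and absent endpoints are reported, not fatal
  net4 <- mk_net(rbind(c("a", "b")), c("a", "b", "z"))
  res4 <- shortest_paths_for_pairs(net4, data.frame(aging_marker = "a",
                                                    disease_marker = "z"))
  expect_equal(res4$skipped$reason, "unreachable")
})

test_that("path lengths equal exhaustive enumeration on small random graphs", {
  set.seed(81)
  for (rep_i in 1:5) {
    n <- sample(5:8, 1)
    nodes <- paste0("v", seq_len(n))
    full <- t(combn(nodes, 2))
    pick <- full[runif(nrow(full)) < 0.45, , drop = FALSE]
    if (nrow(pick) == 0) next
    df <- data.frame(gene_a = pick[, 1], gene_b = pick[, 2])
    g <- igraph::graph_from_data_frame(df, directed = FALSE,
                                       vertices = data.frame(name = nodes))
    net <- list(edges = df, graph = g, degree = igraph::degree(g))
    pairs <- data.frame(aging_marker = nodes[1], disease_marker = nodes[n])
    got <- shortest_paths_for_pairs(net, pairs)
    ## brute force over all simple paths
    ap <- igraph::all_simple_paths(g, from = nodes[1], to = nodes[n])
    if (length(ap) == 0) {
      expect_equal(nrow(got$skipped), 1)
    } else {
      best <- min(lengths(ap)) - 1
      expect_equal(got$lengths, best)
      ## triangle inequality over sampled triples
      D <- igraph::distances(g)
      for (t_i in 1:5) {
        tri <- sample(nodes, 3)
        d <- D[tri, tri]
        if (all(is.finite(d)))
          expect_lte(d[1, 3], d[1, 2] + d[2, 3])
      }
    }
  }
})
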