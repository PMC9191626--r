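## Score-conditioned differential co-expression network: sign-flip edge
## rule, scale-free check, cross-cohort Fisher validation, and
## lexicographically deterministic shortest paths.

#' Per-pair correlation statistics within disease and control groups
#'
#' For every unordered gene pair: Pearson correlation within each group,
#' first-order partial correlation conditioning on the inflamm-aging score
#' within each group, two-sided tests of each coefficient against zero
#' (Fisher z), and two-sided Fisher z-tests of the between-group difference
#' of each quantity. All p families are BH-adjusted over all pairs.
#'
#' @param X Genes x samples matrix (the genes to network).
#' @param score Inflamm-aging score per sample.
#' @param disease Binary label per sample (1 = disease group).
#' @return Data.frame with one row per unordered pair: gene_a, gene_b, the
#'   four coefficients, dcorr/dpcorr differences, coefficient p-values and
#'   FDRs (p_corr = smaller of the two group coefficient p's, likewise
#'   p_pcorr), and difference-test p-values/FDRs (p_dcorr, p_dpcorr).
#' @export
groupwise_edge_statistics <- function(X, score, disease) {
  X <- as.matrix(X)
  stopifnot(length(score) == ncol(X), length(disease) == ncol(X))
  idx_d <- which(disease == 1); idx_c <- which(disease == 0)
  if (length(idx_d) < 4 || length(idx_c) < 4)
    stop("groupwise_edge_statistics: both groups need >= 4 samples")

  group_mats <- function(idx) {
    M <- t(X[, idx, drop = FALSE]); s <- score[idx]
    sds <- apply(M, 2, stats::sd)
    const <- sds == 0
    if (any(const))
      message("groupwise_edge_statistics: ", sum(const),
              " constant gene(s) in a group; their pairs are skipped")
    C <- suppressWarnings(stats::cor(M))
    rs <- as.vector(suppressWarnings(stats::cor(M, s)))
    den <- sqrt(outer(pmax(1 - rs^2, 1e-12), pmax(1 - rs^2, 1e-12)))
    P <- (C - outer(rs, rs)) / den
    C[const, ] <- NA; C[, const] <- NA
    P[const, ] <- NA; P[, const] <- NA
    list(C = C, P = P, n = length(idx))
  }
  gd <- group_mats(idx_d); gc_ <- group_mats(idx_c)

  ut <- which(upper.tri(gd$C), arr.ind = TRUE)
  clamp <- function(r) pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  fisher_diff_p <- function(r1, r2, n1, n2, k) {
    se <- sqrt(1 / (n1 - 3 - k) + 1 / (n2 - 3 - k))
    z <- (atanh(clamp(r1)) - atanh(clamp(r2))) / se
    2 * stats::pnorm(-abs(z))
  }
  res <- data.frame(
    gene_a = rownames(X)[ut[, 1]], gene_b = rownames(X)[ut[, 2]],
    corr_dis = gd$C[ut], corr_ctl = gc_$C[ut],
    pcorr_dis = gd$P[ut], pcorr_ctl = gc_$P[ut],
    stringsAsFactors = FALSE
  )
  res$dcorr <- res$corr_dis - res$corr_ctl
  res$dpcorr <- res$pcorr_dis - res$pcorr_ctl
  ## coefficient tests (r != 0 within group), Fisher z
  coef_p <- function(r, n, k) 2 * stats::pnorm(-abs(atanh(clamp(r))) * sqrt(n - 3 - k))
  res$p_corr <- pmin(coef_p(res$corr_dis, gd$n, 0), coef_p(res$corr_ctl, gc_$n, 0))
  res$p_pcorr <- pmin(coef_p(res$pcorr_dis, gd$n, 1), coef_p(res$pcorr_ctl, gc_$n, 1))
  res$fdr_corr <- stats::p.adjust(res$p_corr, "BH")
  res$fdr_pcorr <- stats::p.adjust(res$p_pcorr, "BH")
  ## group-difference tests
  res$p_dcorr <- fisher_diff_p(res$corr_dis, res$corr_ctl, gd$n, gc_$n, 0)
  res$p_dpcorr <- fisher_diff_p(res$pcorr_dis, res$pcorr_ctl, gd$n, gc_$n, 1)
  res$fdr_dcorr <- stats::p.adjust(res$p_dcorr, "BH")
  res$fdr_dpcorr <- stats::p.adjust(res$p_dpcorr, "BH")
  res
}

#' Build the differential network from edge statistics
#'
#' An edge is kept iff the signs of the correlation difference and the
#' partial-correlation difference disagree (sign 0 never passes) and the
#' statistical filter holds at p < `p_max` and BH FDR < `fdr_max`. With
#' `edge_test = "coefficient"` (default) the filter applies to the
#' within-group coefficient tests (a significant correlation and a
#' significant partial correlation must exist among the two groups); with
#' `"difference"` it applies to the Fisher z-tests of the group differences
#' themselves.
#'
#' @param edge_stats Output of [groupwise_edge_statistics()].
#' @param p_max,fdr_max Thresholds (defaults 0.05 / 0.1).
#' @param edge_test `"coefficient"` or `"difference"`.
#' @return A `differential_network`: list with `edges` (data.frame), `graph`
#'   (igraph, all tested genes as nodes), `degree` (named vector).
#' @export
build_differential_network <- function(edge_stats, p_max = 0.05, fdr_max = 0.1,
                                       edge_test = c("coefficient", "difference")) {
  edge_test <- match.arg(edge_test)
  s1 <- sign(edge_stats$dcorr); s2 <- sign(edge_stats$dpcorr)
  sig <- if (edge_test == "coefficient") {
    edge_stats$p_corr < p_max & edge_stats$p_pcorr < p_max &
      edge_stats$fdr_corr < fdr_max & edge_stats$fdr_pcorr < fdr_max
  } else {
    edge_stats$p_dcorr < p_max & edge_stats$p_dpcorr < p_max &
      edge_stats$fdr_dcorr < fdr_max & edge_stats$fdr_dpcorr < fdr_max
  }
  keep <- !is.na(s1) & !is.na(s2) & (s1 * s2 < 0) & sig
  keep[is.na(keep)] <- FALSE
  edges <- edge_stats[keep, , drop = FALSE]
  nodes <- sort(unique(c(edge_stats$gene_a, edge_stats$gene_b)))
  g <- igraph::graph_from_data_frame(edges[, c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  deg <- igraph::degree(g)
  structure(list(edges = edges, graph = g, degree = deg),
            class = "differential_network")
}

#' @export
print.differential_network <- function(x, ...) {
  cat(sprintf("differential_network: %d nodes, %d edges (%d non-isolated)\n",
              length(x$degree), nrow(x$edges), sum(x$degree > 0)))
  invisible(x)
}

#' Scale-free check via log-log degree-frequency correlation
#'
#' Pearson correlation of log10(degree) against log10(frequency of that
#' degree) over the observed positive degrees; markedly negative r with a
#' small p indicates power-law-like decay.
#'
#' @param network A `differential_network` (or a named degree vector).
#' @return List: `r`, `p_value`, `n_degrees`.
#' @export
scale_free_check <- function(network) {
  deg <- if (inherits(network, "differential_network")) network$degree else network
  deg <- deg[deg > 0]
  tab <- table(deg)
  if (length(tab) < 3)
    stop("scale_free_check: need >= 3 distinct degrees, got ", length(tab))
  x <- log10(as.numeric(names(tab)))
  y <- log10(as.numeric(tab))
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p_value = ct$p.value, n_degrees = length(tab))
}

#' Cross-cohort network validation by Fisher's exact test
#'
#' Builds the 2x2 table of edge membership (train x test) over all tested
#' pairs and returns the one-sided (positive association) Fisher p.
#'
#' @param train_net,test_net `differential_network`s over the same genes.
#' @param n_universe Total number of tested pairs (defaults to choose(nodes, 2)).
#' @return List: `p_value`, `table`, `odds_ratio`.
#' @export
cross_cohort_validation <- function(train_net, test_net, n_universe = NULL) {
  key <- function(net) paste(pmin(net$edges$gene_a, net$edges$gene_b),
                             pmax(net$edges$gene_a, net$edges$gene_b))
  e1 <- key(train_net); e2 <- key(test_net)
  if (!length(e1) || !length(e2))
    stop("cross_cohort_validation: empty network")
  if (is.null(n_universe)) n_universe <- choose(length(train_net$degree), 2)
  both <- length(intersect(e1, e2))
  tab <- matrix(c(both, length(e1) - both,
                  length(e2) - both,
                  n_universe - length(e1) - length(e2) + both), 2, 2)
  ft <- stats::fisher.test(tab, alternative = "greater")
  list(p_value = ft$p.value, table = tab, odds_ratio = unname(ft$estimate))
}

#' Deterministic shortest paths for aging-disease pairs
#'
#' Unit edge weights (path length = hop count). Among equal-length shortest
#' paths the lexicographically smallest node sequence is returned, obtained
#' by walking greedily from the source to the smallest-id neighbor that
#' still lies on a shortest path. Unreachable or absent endpoints are
#' reported in the `skipped` component.
#'
#' @param network A `differential_network`.
#' @param pairs Data.frame with columns `aging_marker`, `disease_marker`
#'   (e.g. [retained_pairs()] of a `causal_pair_set`).
#' @return List: `paths` (list of character node vectors), `lengths`
#'   (edge counts), `skipped` (data.frame of pair + reason).
#' @export
shortest_paths_for_pairs <- function(network, pairs) {
  g <- network$graph
  nodes <- igraph::V(g)$name
  paths <- list(); lengths <- integer(0)
  skipped <- data.frame(aging_marker = character(0),
                        disease_marker = character(0),
                        reason = character(0), stringsAsFactors = FALSE)
  dist_cache <- new.env(parent = emptyenv())
  dist_to <- function(target) {
    if (!is.null(dist_cache[[target]])) return(dist_cache[[target]])
    d <- as.vector(igraph::distances(g, v = target))
    names(d) <- nodes
    dist_cache[[target]] <- d
    d
  }
  adj <- lapply(igraph::as_adj_list(g), function(v) nodes[as.integer(v)])
  names(adj) <- nodes
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$aging_marker[i]; b <- pairs$disease_marker[i]
    if (!(a %in% nodes) || !(b %in% nodes)) {
      warning("shortest_paths_for_pairs: endpoint not in network: ",
              if (a %in% nodes) b else a)
      skipped <- rbind(skipped, data.frame(aging_marker = a, disease_marker = b,
                                           reason = "absent"))
      next
    }
    d <- dist_to(b)
    if (!is.finite(d[a])) {
      skipped <- rbind(skipped, data.frame(aging_marker = a, disease_marker = b,
                                           reason = "unreachable"))
      next
    }
    path <- a
    cur <- a
    while (cur != b) {
      nb <- sort(adj[[cur]])
      nb <- nb[is.finite(d[nb]) & d[nb] == d[cur] - 1]
      cur <- nb[1]
      path <- c(path, cur)
    }
    paths[[length(paths) + 1L]] <- path
    lengths <- c(lengths, length(path) - 1L)
  }
  list(paths = paths, lengths = lengths, skipped = skipped)
}
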