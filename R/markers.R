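## Betweenness-based network markers on the union of aging-disease shortest
## paths, with a permutation null over random gene pairs.

#' Path-set betweenness of genes
#'
#' Counts, for each gene, the number of paths in which it appears as an
#' interior node (endpoints accrue nothing). Sorted descending, ties by
#' gene id.
#'
#' @param paths List of character node vectors.
#' @return Data.frame: gene, betweenness; descending.
#' @export
path_betweenness <- function(paths) {
  interior <- unlist(lapply(paths, function(p)
    if (length(p) > 2) p[-c(1, length(p))] else character(0)))
  if (!length(interior))
    return(data.frame(gene = character(0), betweenness = integer(0)))
  tab <- table(interior)
  out <- data.frame(gene = names(tab), betweenness = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$betweenness, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Permutation test of top betweenness genes against random pair paths
#'
#' Each permutation draws `n_pairs` random node pairs from the network
#' (distinct within a pair), computes their shortest paths, and tallies
#' path-set betweenness; disconnected draws are skipped within the
#' permutation. For each gene of interest,
#' perm_p = (1 + #\{permutations with null betweenness >= observed\}) /
#' (1 + n_perm).
#'
#' @param network A `differential_network`.
#' @param observed Data.frame from [path_betweenness()] on the observed
#'   paths (genes absent from it count as betweenness 0).
#' @param n_pairs Number of random pairs per permutation (same as the
#'   observed aging-disease pair count).
#' @param top_genes Genes to test (default: all genes of `observed`).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed for the draws.
#' @param endpoint_pools Optional list of two character vectors; when given,
#'   the first element of each random pair is drawn from the first pool and
#'   the second from the second (endpoint-stratified null).
#' @return Data.frame: gene, betweenness, perm_p.
#' @export
betweenness_permutation <- function(network, observed, n_pairs,
                                    top_genes = NULL, n_perm = 1000,
                                    seed = 1L, endpoint_pools = NULL) {
  stopifnot(n_pairs >= 1)
  g <- network$graph
  nodes <- igraph::V(g)$name
  if (is.null(top_genes)) top_genes <- observed$gene
  obs <- stats::setNames(rep(0L, length(top_genes)), top_genes)
  hit <- intersect(top_genes, observed$gene)
  obs[hit] <- observed$betweenness[match(hit, observed$gene)]

  D <- igraph::distances(g)
  adj <- lapply(igraph::as_adj_list(g), function(v) nodes[as.integer(v)])
  names(adj) <- nodes
  walk <- function(a, b) {
    d <- D[, b]
    path <- a; cur <- a
    while (cur != b) {
      nb <- sort(adj[[cur]])
      nb <- nb[is.finite(d[nb]) & d[nb] == d[cur] - 1]
      cur <- nb[1]
      path <- c(path, cur)
    }
    path
  }

  exceed <- stats::setNames(rep(0L, length(top_genes)), top_genes)
  with_seed(substream_seed(seed, "betweenness_perm"), {
    for (b in seq_len(n_perm)) {
      tally <- new.env(parent = emptyenv())
      for (pi in seq_len(n_pairs)) {
        if (is.null(endpoint_pools)) {
          pr <- sample(nodes, 2)
        } else {
          pr <- c(sample(endpoint_pools[[1]], 1), sample(endpoint_pools[[2]], 1))
          if (pr[1] == pr[2]) next
        }
        if (!is.finite(D[pr[1], pr[2]])) next
        p <- walk(pr[1], pr[2])
        if (length(p) > 2) for (gn in p[-c(1, length(p))]) {
          tally[[gn]] <- (tally[[gn]] %||% 0L) + 1L
        }
      }
      null_b <- vapply(top_genes, function(gn) tally[[gn]] %||% 0L, integer(1))
      exceed <- exceed + as.integer(null_b >= obs)
    }
  })
  data.frame(gene = top_genes, betweenness = as.integer(obs),
             perm_p = (1 + exceed) / (1 + n_perm),
             row.names = NULL, stringsAsFactors = FALSE)
}
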