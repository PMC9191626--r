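## Hypergeometric enrichment of shortest paths against GMT gene sets,
## BH control, and the sum-of-(1-FDR) enrichment score.

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes. Duplicate genes within a set are collapsed.
#'
#' @param path Path to a GMT file.
#' @return Named list of unique gene-id vectors, with set descriptions in
#'   attribute `"descriptions"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT parse error at line ", i, ": need name, description, and >= 1 gene")
    sets[[f[1]]] <- unique(f[-(1:2)])
    desc[f[1]] <- f[2]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of gene-id vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions (defaults to "na").
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[nm] %||% "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for drawing `n` genes from a universe of `N` containing `M`
#' set members; k = 0 returns exactly 1.
#'
#' @param N Universe size.
#' @param M Gene-set size within the universe.
#' @param n Number of genes drawn (path size).
#' @param k Observed overlap.
#' @return Probability in (0, 1].
#' @export
hypergeom_upper_tail <- function(N, M, n, k) {
  if (M > N || n > N || k < 0 || k > min(M, n))
    stop("hypergeom_upper_tail: arguments violate 0 <= k <= min(M,n), M,n <= N")
  if (k == 0) return(1)
  stats::phyper(k - 1, M, N - M, n, lower.tail = FALSE)
}

#' Enrich shortest paths against gene sets
#'
#' Tests every (path, term) combination with [hypergeom_upper_tail()]
#' (N = universe size, M = set size within the universe, n = path gene
#' count, k = overlap), BH-adjusts over the chosen family, and scores each
#' term as the sum of (1 - FDR) over its qualifying paths (p < `p_max` and
#' FDR < `fdr_max`). Terms are ranked by qualifying-path count, then score.
#'
#' @param paths List of character gene-id vectors (path node lists).
#' @param genesets Named list of gene-id vectors (e.g. [read_gmt()]).
#' @param universe Character vector of all eligible genes (must contain all
#'   path genes).
#' @param p_max,fdr_max Qualification thresholds (defaults 0.05 / 0.1).
#' @param bh_family `"per_path"` (BH within each path's term family,
#'   default — each path's p-values are controlled separately) or
#'   `"pooled"` (one family over all path x term tests).
#' @return List: `results` (data.frame term, n_enriched_paths, score,
#'   best_p, best_fdr) and `tests` (per path x term evidence).
#' @export
enrich_paths <- function(paths, genesets, universe, p_max = 0.05,
                         fdr_max = 0.1, bh_family = c("per_path", "pooled")) {
  bh_family <- match.arg(bh_family)
  universe <- unique(universe)
  stray <- setdiff(unique(unlist(paths)), universe)
  if (length(stray))
    stop("enrich_paths: path genes outside the universe: ",
         paste(utils::head(stray, 5), collapse = ", "))
  N <- length(universe)
  sets_u <- lapply(genesets, intersect, y = universe)
  empty <- vapply(sets_u, length, integer(1)) == 0
  if (any(empty))
    message("enrich_paths: skipped ", sum(empty), " term(s) absent from the universe")
  sets_u <- sets_u[!empty]
  if (!length(sets_u) || !length(paths)) {
    return(list(results = data.frame(term = character(0),
                                     n_enriched_paths = integer(0),
                                     score = numeric(0)),
                tests = NULL))
  }
  grid <- expand.grid(path = seq_along(paths), term = names(sets_u),
                      stringsAsFactors = FALSE)
  grid$p <- mapply(function(pi, tm) {
    pg <- unique(paths[[pi]])
    hypergeom_upper_tail(N, length(sets_u[[tm]]), length(pg),
                         length(intersect(pg, sets_u[[tm]])))
  }, grid$path, grid$term)
  grid$fdr <- if (bh_family == "pooled") {
    stats::p.adjust(grid$p, "BH")
  } else {
    stats::ave(grid$p, grid$path, FUN = function(p) stats::p.adjust(p, "BH"))
  }
  grid$qualifies <- grid$p < p_max & grid$fdr < fdr_max
  agg <- do.call(rbind, lapply(split(grid, grid$term), function(d) {
    data.frame(term = d$term[1],
               n_enriched_paths = sum(d$qualifies),
               score = sum(1 - d$fdr[d$qualifies]),
               best_p = min(d$p), best_fdr = min(d$fdr),
               stringsAsFactors = FALSE)
  }))
  agg <- agg[order(-agg$n_enriched_paths, -agg$score, agg$term), ]
  rownames(agg) <- NULL
  list(results = agg, tests = grid)
}
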