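# independent brute-force oracle for the interaction transform
oracle_interaction <- function(X, phenotype) {
  genes <- rownames(X)
  out <- matrix(0, length(genes), ncol(X), dimnames = dimnames(X))
  for (g in genes) {
    others <- setdiff(genes, g)
    rel <- vapply(others, function(j) {
      pr <- X[g, ] * X[j, ]
      if (sd(pr) == 0 || sd(phenotype) == 0) 0 else cor(pr, phenotype)
    }, numeric(1))
    k <- floor(log2(length(others) + 1))
    top <- others[order(-abs(rel), match(others, genes))][seq_len(k)]
    for (j in top) out[g, ] <- out[g, ] + rel[j] * X[g, ] * X[j, ]
  }
  out
}

# exhaustive hypergeometric oracle: enumerate all draws of size n
oracle_upper_tail <- function(N, M, n, k) {
  draws <- combn(N, n)
  members <- seq_len(M)
  hits <- apply(draws, 2, function(d) sum(d %in% members) >= k)
  mean(hits)
}
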