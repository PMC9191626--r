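## Interaction-feature transform, ReliefF ranking, cosine-kNN predictors
## with stratified cross-validation, and the improved inflamm-aging model.

#' Logistic age transform
#'
#' Maps age in years to (0, 1) via 1 / (1 + exp(-(age - 50)/50)); strictly
#' increasing, 0.5 at age 50. Used as the phenotype of the aging model.
#'
#' @param age Non-negative age(s) in years.
#' @return Value(s) in (0, 1).
#' @export
transform_age <- function(age) {
  stopifnot(all(age >= 0))
  stats::plogis((age - 50) / 50)
}

#' Relevance of a gene pair for a phenotype
#'
#' Pearson correlation between the elementwise product gene_i * gene_j and
#' the phenotype. A zero-variance product (or constant phenotype) yields 0
#' with a warning.
#'
#' @param gene_i,gene_j Expression vectors over the same samples (length >= 3).
#' @param phenotype Numeric phenotype per sample (binary disease labels or
#'   transformed age).
#' @return Correlation in \[-1, 1\].
#' @export
relevance <- function(gene_i, gene_j, phenotype) {
  stopifnot(length(gene_i) == length(gene_j),
            length(gene_j) == length(phenotype), length(gene_i) >= 3)
  prod <- gene_i * gene_j
  if (stats::sd(prod) == 0 || stats::sd(phenotype) == 0) {
    warning("relevance: zero-variance product or phenotype; returning 0")
    return(0)
  }
  stats::cor(prod, phenotype)
}

#' Redundancy of a gene pair
#'
#' Plain Pearson correlation between the two expression vectors.
#' @param gene_i,gene_j Expression vectors over the same samples.
#' @return Correlation in \[-1, 1\].
#' @export
redundancy <- function(gene_i, gene_j) stats::cor(gene_i, gene_j)

#' Interaction-feature transform of expression profiles
#'
#' For each anchor gene i, partners j are ranked by |relevance(i, j)|
#' (descending, ties broken by partner order) and the top floor(log2(n+1))
#' are kept, n being the number of available partners. The transformed
#' profile is
#' interaction_i(s) = sum_j relevance(i,j) * gene_i(s) * gene_j(s).
#'
#' @param X Genes x samples expression matrix (rownames = gene ids).
#' @param phenotype Numeric phenotype per sample.
#' @param anchors Gene ids to transform (default: all rows).
#' @param partners Gene ids eligible as partners (default: all rows). The
#'   anchor itself is never its own partner.
#' @return Matrix anchors x samples of interaction features, with attribute
#'   `"partners"`: per-anchor data.frame of partner ids and weights.
#' @export
interaction_transform <- function(X, phenotype, anchors = rownames(X),
                                  partners = rownames(X)) {
  X <- as.matrix(X)
  stopifnot(!is.null(rownames(X)), length(phenotype) == ncol(X))
  anchors <- intersect(anchors, rownames(X))
  partners <- intersect(partners, rownames(X))
  out <- matrix(0, nrow = length(anchors), ncol = ncol(X),
                dimnames = list(anchors, colnames(X)))
  plist <- vector("list", length(anchors))
  names(plist) <- anchors
  pheno_sd <- stats::sd(phenotype)
  for (a in anchors) {
    cand <- setdiff(partners, a)
    ## number kept: floor(log2(n+1)) with n = available partners
    k <- floor(log2(length(cand) + 1))
    if (length(cand) == 0 || k == 0) {
      warning("interaction_transform: anchor ", a,
              " has no partners; feature is all zeros")
      plist[[a]] <- data.frame(partner = character(0), weight = numeric(0))
      next
    }
    P <- X[cand, , drop = FALSE] * rep(X[a, ], each = length(cand))
    rel <- if (pheno_sd == 0) rep(0, length(cand)) else row_cor(P, phenotype)
    rel[is.na(rel)] <- 0
    ord <- order(-abs(rel), seq_along(cand))[seq_len(min(k, length(cand)))]
    out[a, ] <- colSums(P[ord, , drop = FALSE] * rel[ord])
    plist[[a]] <- data.frame(partner = cand[ord], weight = rel[ord],
                             stringsAsFactors = FALSE)
  }
  attr(out, "partners") <- plist
  out
}

#' Deterministic all-instances ReliefF ranking for binary labels
#'
#' Features are range-scaled; every instance contributes the mean absolute
#' feature difference to its `k` nearest misses minus its `k` nearest hits
#' (Manhattan distance on the scaled features; neighbor ties broken by
#' instance order). Higher weight ranks earlier; weight ties keep input order.
#'
#' @param features Samples x features matrix (colnames = feature ids).
#' @param labels Binary vector (two classes present).
#' @param k Number of nearest hits/misses per instance (default 10, capped at
#'   class size - 1).
#' @return Character vector of feature ids, best first, with attribute
#'   `"weights"`.
#' @export
relieff_rank <- function(features, labels, k = 10) {
  features <- as.matrix(features)
  labels <- as.vector(labels)
  stopifnot(nrow(features) == length(labels))
  if (length(unique(labels)) < 2) stop("relieff_rank: need both classes present")
  rng <- apply(features, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1
  S <- sweep(sweep(features, 2, apply(features, 2, min)), 2, rng, "/")
  n <- nrow(S)
  D <- as.matrix(stats::dist(S, method = "manhattan"))
  W <- numeric(ncol(S))
  for (i in seq_len(n)) {
    same <- which(labels == labels[i]); same <- setdiff(same, i)
    diff_cl <- which(labels != labels[i])
    kh <- min(k, length(same)); km <- min(k, length(diff_cl))
    if (kh == 0 || km == 0) next
    hits <- same[order(D[i, same], same)][seq_len(kh)]
    misses <- diff_cl[order(D[i, diff_cl], diff_cl)][seq_len(km)]
    dh <- abs(S[rep(i, kh), , drop = FALSE] - S[hits, , drop = FALSE])
    dm <- abs(S[rep(i, km), , drop = FALSE] - S[misses, , drop = FALSE])
    W <- W + colMeans(dm) - colMeans(dh)
  }
  W <- W / n
  ord <- order(-W, seq_along(W))
  out <- colnames(features)[ord]
  attr(out, "weights") <- stats::setNames(W[ord], out)
  out
}

#' Predictor configuration
#'
#' @param k_neighbors Number of neighbors for the kNN vote (default 5).
#' @param distance Distance metric (only "cosine" is implemented).
#' @param n_folds Cross-validation folds (default 10).
#' @param candidate_feature_counts Increasing feature counts scanned by CV.
#' @param seed Seed controlling fold assignment.
#' @return A `predictor_config` list.
#' @export
predictor_config <- function(k_neighbors = 5, distance = "cosine",
                             n_folds = 10,
                             candidate_feature_counts = c(20, 40, 80, 160),
                             seed = 1L) {
  if (k_neighbors < 1) stop("k_neighbors must be positive")
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (!identical(distance, "cosine")) stop("only the cosine distance is implemented")
  if (is.unsorted(candidate_feature_counts, strictly = TRUE))
    stop("candidate_feature_counts must be strictly increasing")
  structure(list(k_neighbors = as.integer(k_neighbors), distance = distance,
                 n_folds = as.integer(n_folds),
                 candidate_feature_counts = as.integer(candidate_feature_counts),
                 seed = as.integer(seed)),
            class = "predictor_config")
}

#' Cosine-distance kNN class prediction
#'
#' Majority vote over the k nearest training samples by cosine distance;
#' distance ties are broken toward the smaller training index, vote ties
#' toward class 0 (the smaller label).
#'
#' @param train Samples x features training matrix.
#' @param labels Training labels (binary).
#' @param test Samples x features matrix to classify.
#' @param k Number of neighbors.
#' @return Predicted labels for `test` rows.
#' @export
knn_cosine_predict <- function(train, labels, test, k = 5) {
  train <- as.matrix(train); test <- as.matrix(test)
  if (k > nrow(train)) stop("k exceeds the number of training samples")
  D <- cosine_distance(test, train)
  classes <- sort(unique(labels))
  apply_pred <- function(di) {
    nb <- order(di, seq_along(di))[seq_len(k)]
    votes <- table(factor(labels[nb], levels = classes))
    classes[which.max(votes)]   # tie -> first (smaller) class
  }
  out <- apply(D, 1, apply_pred)
  if (is.numeric(labels)) as.numeric(out) else out
}

#' Stratified fold assignment
#' @noRd
stratified_folds <- function(labels, n_folds, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

#' Fit a cosine-kNN predictor with cross-validated feature-count selection
#'
#' For each candidate feature count c, computes stratified `n_folds`-fold CV
#' accuracy of the kNN classifier on the top-c features (features must be in
#' ranked order); `chosen_count` is the smallest count attaining the maximum
#' CV accuracy. The returned model holds the full training data restricted
#' to the chosen features.
#'
#' @param features Samples x features matrix, columns in ranked order.
#' @param labels Binary labels per sample.
#' @param config A [predictor_config()].
#' @return A `knn_model` list: `features` (chosen ids), `chosen_count`,
#'   `cv_curve` (count -> accuracy), `train`, `labels`, `config`.
#' @export
fit_knn_predictor <- function(features, labels, config = predictor_config()) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < config$n_folds) stop("fewer samples than folds")
  counts <- config$candidate_feature_counts
  counts <- counts[counts <= ncol(features)]
  if (!length(counts)) counts <- ncol(features)
  folds <- stratified_folds(labels, config$n_folds, config$seed)
  acc <- numeric(length(counts))
  for (ci in seq_along(counts)) {
    c_ <- counts[ci]
    correct <- 0L
    for (f in seq_len(config$n_folds)) {
      tr <- folds != f; te <- folds == f
      if (!any(te)) next
      if (config$k_neighbors > sum(tr))
        stop("k_neighbors exceeds fold training size")
      pred <- knn_cosine_predict(features[tr, seq_len(c_), drop = FALSE],
                                 labels[tr],
                                 features[te, seq_len(c_), drop = FALSE],
                                 config$k_neighbors)
      correct <- correct + sum(pred == labels[te])
    }
    acc[ci] <- correct / n
  }
  chosen <- counts[which.max(acc)]
  structure(list(
    features = colnames(features)[seq_len(chosen)],
    chosen_count = chosen,
    cv_curve = stats::setNames(acc, counts),
    train = features[, seq_len(chosen), drop = FALSE],
    labels = labels,
    config = config
  ), class = "knn_model")
}

#' @export
predict.knn_model <- function(object, newdata, ...) {
  knn_cosine_predict(object$train, object$labels,
                     as.matrix(newdata)[, object$features, drop = FALSE],
                     object$config$k_neighbors)
}

#' Kruskal-Wallis marker filter
#'
#' Keeps genes whose expression differs between the two groups at p < p_max
#' and BH FDR < fdr_max (family = the genes tested in this call).
#' @noRd
kw_filter_genes <- function(X, groups, p_max = 0.05, fdr_max = 0.2) {
  if (nrow(X) == 0) return(character(0))
  p <- apply(X, 1, function(v) stats::kruskal.test(v, factor(groups))$p.value)
  fdr <- stats::p.adjust(p, "BH")
  rownames(X)[p < p_max & fdr < fdr_max]
}

#' Select markers by interaction transform, ReliefF, and kNN CV
#'
#' The basic (single-phenotype) marker-selection path: transform all genes
#' with [interaction_transform()], rank by [relieff_rank()] against the
#' binary labels, scan feature counts with [fit_knn_predictor()], and return
#' the chosen top genes.
#'
#' @param study A preprocessed `expression_study` (training split is used).
#' @param phenotype `"aging"` (transformed age as relevance phenotype, old
#'   vs young labels) or `"disease"` (disease labels for both).
#' @param config A [predictor_config()].
#' @param use_interactions Set FALSE for the traditional predictor on raw
#'   gene profiles (comparison mode).
#' @return List: `markers`, `ranking`, `model` (a `knn_model`).
#' @export
select_markers <- function(study, phenotype = c("disease", "aging"),
                           config = predictor_config(),
                           use_interactions = TRUE) {
  phenotype <- match.arg(phenotype)
  tr <- study$split == "train"
  X <- study$expression[, tr, drop = FALSE]
  if (phenotype == "aging") {
    pheno <- transform_age(study$age[tr])
    labels <- as.integer(study$age[tr] > 50)
  } else {
    pheno <- study$disease[tr]
    labels <- study$disease[tr]
  }
  F <- if (use_interactions) interaction_transform(X, pheno) else X
  ranked <- relieff_rank(t(F), labels)
  model <- fit_knn_predictor(t(F)[, ranked, drop = FALSE], labels, config)
  list(markers = model$features, ranking = ranked, model = model)
}

#' Build the improved inflamm-aging marker model
#'
#' Integrates aging, inflammatory, and disease markers:
#' (1) candidate inflammatory markers are intersected with the study's genes
#' and removed from the aging/disease candidate lists; (2) candidates are
#' filtered by Kruskal-Wallis (p < 0.05, BH FDR < 0.2) — aging candidates
#' between old and young samples, disease candidates between disease and
#' control; (3) inflamm-aging markers are the inflammatory
#' markers whose interaction transform (partners restricted to the aging
#' markers, transformed-age phenotype) survives the same KW filter;
#' (4) disease candidates are re-transformed with partners restricted to the
#' inflammatory markers (disease phenotype); (5) ReliefF + kNN CV re-selects
#' the final disease markers over the top min(500, available) candidates,
#' with inflamm-aging-transformed versions replacing the originals.
#'
#' @param study Preprocessed `expression_study` (training split used for all
#'   fitting).
#' @param inflammatory_geneset Character vector of candidate inflammatory
#'   gene ids (e.g. from [read_gmt()]).
#' @param aging_markers Candidate aging marker ids.
#' @param candidate_disease_markers Candidate disease marker ids (ranked).
#' @param config A [predictor_config()].
#' @return A `marker_model` list: `aging_markers`, `inflammatory_markers`,
#'   `disease_markers`, `feature_ranking`, `cv_curve`, `chosen_count`,
#'   `interaction_partners`.
#' @export
build_improved_model <- function(study, inflammatory_geneset, aging_markers,
                                 candidate_disease_markers,
                                 config = predictor_config()) {
  if (!length(inflammatory_geneset)) stop("empty inflammatory gene set")
  tr <- study$split == "train"
  X <- study$expression[, tr, drop = FALSE]
  disease <- study$disease[tr]
  t_age <- transform_age(study$age[tr])

  ## step 1: restrict inflammatory candidates to the study; de-overlap
  inflammatory <- intersect(inflammatory_geneset, rownames(X))
  if (!length(inflammatory)) stop("stage 1: no inflammatory candidates present in study")
  aging <- setdiff(intersect(aging_markers, rownames(X)), inflammatory)
  dis_cand <- setdiff(intersect(candidate_disease_markers, rownames(X)),
                      inflammatory)

  ## step 2: Kruskal-Wallis filter — aging candidates between age groups
  ## (old vs young), disease candidates between disease and control
  old <- as.integer(study$age[tr] > 50)
  aging <- kw_filter_genes(X[aging, , drop = FALSE], old)
  dis_cand <- kw_filter_genes(X[dis_cand, , drop = FALSE], disease)
  if (!length(aging)) stop("stage 2: no aging markers survive the Kruskal-Wallis filter")
  if (!length(dis_cand)) stop("stage 2: no disease candidates survive the Kruskal-Wallis filter")

  ## step 3: inflamm-aging markers = transformed inflammatory markers
  ia_feat <- interaction_transform(X, t_age, anchors = inflammatory,
                                   partners = aging)
  ia_keep <- kw_filter_genes(ia_feat, disease)
  if (!length(ia_keep)) stop("stage 3: no inflamm-aging markers survive the Kruskal-Wallis filter")

  ## step 4: disease candidates re-transformed on inflammatory partners
  dis_feat <- interaction_transform(X, disease, anchors = dis_cand,
                                    partners = inflammatory)

  ## step 5: ReliefF + kNN CV over top-500 candidates with transformed
  ## versions replacing the originals
  pool <- dis_cand[seq_len(min(500L, length(dis_cand)))]
  F <- X[pool, , drop = FALSE]
  has_ia <- intersect(pool, rownames(dis_feat))
  F[has_ia, ] <- dis_feat[has_ia, , drop = FALSE]
  ranked <- relieff_rank(t(F), disease)
  model <- fit_knn_predictor(t(F)[, ranked, drop = FALSE], disease, config)

  structure(list(
    aging_markers = aging,
    inflammatory_markers = ia_keep,
    disease_markers = model$features,
    feature_ranking = ranked,
    cv_curve = model$cv_curve,
    chosen_count = model$chosen_count,
    interaction_partners = attr(dis_feat, "partners"),
    model = model
  ), class = "marker_model")
}
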